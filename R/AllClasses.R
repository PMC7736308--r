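.ATOM_COLS <- c("serial", "name", "element", "resname", "chain", "resno",
                "x", "y", "z")

.checkAtoms <- function(atoms) {
  missing <- setdiff(.ATOM_COLS, names(atoms))
  if (length(missing))
    return(paste("atoms is missing columns:", paste(missing, collapse = ", ")))
  xyz <- as.matrix(atoms[, c("x", "y", "z")])
  if (nrow(atoms) && !all(is.finite(xyz)))
    return("atom positions must be finite")
  key <- paste(atoms$chain, atoms$resno, atoms$name, sep = "|")
  if (anyDuplicated(key))
    return("(chain, resno, name) must be unique within a model")
  TRUE
}

#' Single atomic model
#'
#' Holds one set of atomic coordinates as an ordered atom table. Column
#' \code{resno} carries author residue numbering exactly as read from the
#' source file; no renumbering is ever applied, so residue-range definitions
#' (e.g. POTRA1 = residues 24--92) can be used verbatim.
#'
#' @slot modelId character scalar identifying the model.
#' @slot atoms data.frame with columns \code{serial}, \code{name},
#'   \code{element}, \code{resname}, \code{chain}, \code{resno}, \code{x},
#'   \code{y}, \code{z} (coordinates in Angstrom). An optional \code{vdw}
#'   column overrides the element-based van der Waals radius table where
#'   present (used by pseudo-atom fixtures).
#'
#' @exportClass StructureModel
setClass("StructureModel",
         representation(modelId = "character", atoms = "data.frame"),
         validity = function(object) {
           if (length(object@modelId) != 1L) return("modelId must be length 1")
           .checkAtoms(object@atoms)
         })

#' Ensemble of atomic models
#'
#' An ordered collection of \linkS4class{StructureModel} objects with unique
#' model ids, e.g. the members of a structural ensemble fitted into related
#' cryo-EM maps.
#'
#' @slot models list of \linkS4class{StructureModel}.
#' @slot label character scalar describing the ensemble.
#'
#' @exportClass ModelEnsemble
setClass("ModelEnsemble",
         representation(models = "list", label = "character"),
         prototype(label = ""),
         validity = function(object) {
           if (!length(object@models)) return("ensemble must be non-empty")
           if (!all(vapply(object@models, is, logical(1), "StructureModel")))
             return("all models must be StructureModel objects")
           ids <- vapply(object@models, function(m) m@modelId, character(1))
           if (anyDuplicated(ids)) return("model ids must be unique")
           TRUE
         })

#' Trajectory frame series
#'
#' A \linkS4class{ModelEnsemble} whose members are successive coordinate
#' snapshots of the same system: every frame must contain exactly the same
#' atoms (same \code{chain}, \code{resno}, \code{name} in the same order).
#'
#' @slot frameStrideNote free-text note on how frames were extracted.
#'
#' @exportClass TrajectoryFrames
setClass("TrajectoryFrames",
         contains = "ModelEnsemble",
         representation(frameStrideNote = "character"),
         prototype(frameStrideNote = ""),
         validity = function(object) {
           keys <- lapply(object@models, function(m)
             paste(m@atoms$chain, m@atoms$resno, m@atoms$name, sep = "|"))
           if (length(unique(vapply(keys, paste, character(1),
                                    collapse = "\r"))) != 1L)
             return("all frames must share identical atom ordering and identity")
           TRUE
         })

#' Aggregated bilayer-thickness grid
#'
#' Per-cell mean and population standard deviation of bilayer thickness over
#' a set of trajectory frames, sampled on a square grid in the central-plane
#' coordinate system of the first frame. Statistics are defined only where
#' \code{mask} is \code{TRUE} (cells inside the nanodisc).
#'
#' @slot x,y cell-centre coordinates (Angstrom) along the two in-plane axes.
#' @slot spacing grid spacing in Angstrom.
#' @slot mask logical matrix, \code{length(x)} x \code{length(y)}.
#' @slot mean,sd numeric matrices of the same shape (Angstrom; \code{NA}
#'   outside the mask).
#' @slot perFrame list of per-frame thickness matrices (may be empty).
#' @slot nFrames number of frames aggregated.
#'
#' @exportClass ThicknessGrid
setClass("ThicknessGrid",
         representation(x = "numeric", y = "numeric", spacing = "numeric",
                        mask = "matrix", mean = "matrix", sd = "matrix",
                        perFrame = "list", nFrames = "integer"),
         validity = function(object) {
           dm <- c(length(object@x), length(object@y))
           if (!identical(dim(object@mask), dm)) return("mask shape mismatch")
           if (!identical(dim(object@mean), dm)) return("mean shape mismatch")
           if (!identical(dim(object@sd), dm)) return("sd shape mismatch")
           sd <- object@sd[object@mask]
           if (any(!is.na(sd) & sd < 0)) return("sd must be non-negative")
           TRUE
         })

#' Scaffold-belt planarity profile
#'
#' Per-residue deviation-from-planarity score for one membrane-scaffold
#' belt: for each frame a plane is fitted to the belt C-alpha atoms, the
#' Euclidean distance of each C-alpha from its projection onto that plane is
#' accumulated over frames, and the score is log10 of the per-residue sum.
#'
#' @slot resno author residue numbers of the belt C-alpha trace.
#' @slot score per-residue log10 summed deviation (see
#'   \code{\link{planarityProfile}} for the zero-deviation floor).
#' @slot nFrames number of frames summed.
#' @slot chain chain identifier of the belt.
#'
#' @exportClass PlanarityProfile
setClass("PlanarityProfile",
         representation(resno = "integer", score = "numeric",
                        nFrames = "integer", chain = "character"),
         validity = function(object) {
           if (length(object@resno) != length(object@score))
             return("one score per belt residue required")
           TRUE
         })

#' Photon-burst table
#'
#' Detected fluorescence bursts from an alternating-laser-excitation photon
#' stream, with per-burst photon counts split by detection channel and
#' excitation slot, the raw proximity ratio, and (after
#' \code{\link{correctBursts}}) corrected FRET efficiency and stoichiometry.
#'
#' @slot bursts data.frame with one row per burst: \code{start}, \code{end}
#'   (microseconds), \code{nPhotons}, \code{FDD}, \code{FDA}, \code{FAA},
#'   \code{Eraw}, and after correction \code{Ecorr}, \code{S}, \code{valid}.
#' @slot params list of detection/correction parameters used.
#'
#' @exportClass BurstTable
setClass("BurstTable",
         representation(bursts = "data.frame", params = "list"),
         validity = function(object) {
           need <- c("start", "end", "nPhotons", "FDD", "FDA", "FAA")
           missing <- setdiff(need, names(object@bursts))
           if (length(missing))
             return(paste("bursts missing columns:",
                          paste(missing, collapse = ", ")))
           cnt <- as.matrix(object@bursts[, c("FDD", "FDA", "FAA")])
           if (nrow(cnt) && any(cnt < 0)) return("photon counts must be >= 0")
           TRUE
         })

#' Dye accessible-volume cloud
#'
#' The set of sterically allowed dye positions for a dye attached at a given
#' residue, enumerated on a cubic grid (single-sphere accessible-volume
#' approximation). Points carry uniform weight.
#'
#' @slot points numeric matrix, one allowed dye position per row (Angstrom).
#' @slot attachment coordinates of the attachment atom.
#' @slot params the \code{\link{dyeParams}} list used.
#'
#' @exportClass DyeCloud
setClass("DyeCloud",
         representation(points = "matrix", attachment = "numeric",
                        params = "list"),
         validity = function(object) {
           if (ncol(object@points) != 3L) return("points must be n x 3")
           if (length(object@attachment) != 3L)
             return("attachment must be a 3-vector")
           TRUE
         })

#' Domain COM displacement result
#'
#' Pairwise centre-of-mass displacement statistics for a set of domains
#' across a superposed model ensemble.
#'
#' @slot domains domain names.
#' @slot matrices named list (one per domain) of symmetric model-by-model
#'   COM distance matrices in Angstrom.
#' @slot maxima named numeric vector of per-domain maximum displacements.
#' @slot coms named list (one per domain) of model-by-3 COM coordinate
#'   matrices in the common (reference-aligned) frame.
#' @slot scheme character description of the alignment scheme used.
#'
#' @exportClass DisplacementResult
setClass("DisplacementResult",
         representation(domains = "character", matrices = "list",
                        maxima = "numeric", coms = "list",
                        scheme = "character"),
         validity = function(object) {
           for (m in object@matrices) {
             if (!isSymmetric(unname(m), tol = 1e-8))
               return("distance matrices must be symmetric")
             if (any(diag(m) != 0)) return("distance matrices need zero diagonal")
             if (any(m < 0)) return("distances must be non-negative")
           }
           TRUE
         })

setMethod("show", "StructureModel", function(object) {
  cat("StructureModel '", object@modelId, "': ", nrow(object@atoms),
      " atoms, ", length(unique(object@atoms$chain)), " chain(s)\n", sep = "")
})

setMethod("show", "ModelEnsemble", function(object) {
  cat(class(object), if (nzchar(object@label)) paste0(" '", object@label, "'"),
      ": ", length(object@models), " model(s), ",
      nrow(object@models[[1]]@atoms), " atoms in model 1\n", sep = "")
})

setMethod("show", "ThicknessGrid", function(object) {
  cat("ThicknessGrid: ", length(object@x), " x ", length(object@y),
      " cells at ", object@spacing, " A spacing, ", sum(object@mask),
      " in-disc cells, ", object@nFrames, " frame(s)\n", sep = "")
  v <- object@mean[object@mask]
  cat("  mean thickness ", sprintf("%.2f", mean(v)), " A (range ",
      sprintf("%.2f", min(v)), "-", sprintf("%.2f", max(v)), ")\n", sep = "")
})

setMethod("show", "PlanarityProfile", function(object) {
  cat("PlanarityProfile: chain ", object@chain, ", ", length(object@resno),
      " residues over ", object@nFrames, " frame(s); score range ",
      sprintf("%.3f", min(object@score)), " to ",
      sprintf("%.3f", max(object@score)), "\n", sep = "")
})

setMethod("show", "BurstTable", function(object) {
  cat("BurstTable: ", nrow(object@bursts), " burst(s)", sep = "")
  if ("Ecorr" %in% names(object@bursts))
    cat(", corrected (gamma=", object@params$gamma, ")", sep = "")
  cat("\n")
})

setMethod("show", "DyeCloud", function(object) {
  cat("DyeCloud: ", nrow(object@points), " allowed positions, linker ",
      object@params$linkerLength, " A\n", sep = "")
})

setMethod("show", "DisplacementResult", function(object) {
  cat("DisplacementResult (", object@scheme, "): ", length(object@domains),
      " domain(s) x ", nrow(object@matrices[[1]]), " models\n", sep = "")
  for (d in object@domains)
    cat(sprintf("  %-8s max displacement %.2f A\n", d, object@maxima[[d]]))
})
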