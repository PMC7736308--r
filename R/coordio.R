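#' Read a (multi-)model PDB file into a ModelEnsemble
#'
#' Parses a PDB coordinate file and returns one \linkS4class{StructureModel}
#' per MODEL record (a file without MODEL records yields exactly one model).
#' Author residue numbering is preserved verbatim. Alternate-location
#' indicators other than '' or 'A' are dropped so that downstream centre-of-
#' mass and RMSD calculations never double-count atoms. Hydrogens are
#' retained (contact and accessible-volume analyses exclude them at their
#' own level).
#'
#' @param path path to a PDB file.
#' @param format file format; only \code{"pdb"} is supported.
#' @param label ensemble label (defaults to the file name).
#' @return a \linkS4class{ModelEnsemble}.
#' @seealso \code{\link{writeModels}}, \code{\link{selectAtoms}}
#' @export
readModels <- function(path, format = c("pdb"), label = basename(path)) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("cannot read file: ", path)
  pdb <- tryCatch(bio3d::read.pdb(path, multi = TRUE, verbose = FALSE),
                  error = function(e) stop("failed to parse PDB: ",
                                           conditionMessage(e)))
  atom <- pdb$atom
  if (is.null(atom) || nrow(atom) == 0L) stop("file contains zero atoms")
  keep <- is.na(atom$alt) | atom$alt %in% c("", "A")
  atom <- atom[keep, , drop = FALSE]
  if (nrow(atom) == 0L) stop("file contains zero atoms after altloc filter")
  element <- atom$elesy
  blank <- is.na(element) | !nzchar(trimws(element))
  if (any(blank))
    element[blank] <- suppressWarnings(
      bio3d::atom2ele(atom$elety[blank], rescue = TRUE))
  chain <- atom$chain
  chain[is.na(chain)] <- ""
  nModel <- nrow(pdb$xyz)
  idx3 <- as.vector(t(outer(which(keep) - 1L, 1:3,
                            function(i, j) 3L * i + j)))
  mods <- lapply(seq_len(nModel), function(k) {
    xyz <- matrix(pdb$xyz[k, idx3], ncol = 3, byrow = TRUE)
    newModel(k, atomTable(atom$eleno, atom$elety, toupper(element),
                          atom$resid, chain, atom$resno, xyz))
  })
  new("ModelEnsemble", models = mods, label = label)
}

#' Select atoms from a model
#'
#' Order-preserving filter over the atom table of a
#' \linkS4class{StructureModel}: atoms matching the requested chain, inclusive
#' residue-number range (author numbering) and atom-name set are returned in
#' their original order. \code{NULL} for any criterion means "match all".
#' An empty result is returned as an empty data.frame, not an error.
#'
#' @param model a \linkS4class{StructureModel}.
#' @param chain chain identifier(s), or \code{NULL} for any.
#' @param residueRange inclusive \code{c(lo, hi)} residue-number range, or
#'   \code{NULL} for any.
#' @param atomNames character vector of atom names (e.g. \code{"CA"}), or
#'   \code{NULL} for any.
#' @return data.frame of matching atom records.
#' @export
selectAtoms <- function(model, chain = NULL, residueRange = NULL,
                        atomNames = NULL) {
  stopifnot(is(model, "StructureModel"))
  a <- model@atoms
  keep <- rep(TRUE, nrow(a))
  if (!is.null(chain)) keep <- keep & a$chain %in% chain
  if (!is.null(residueRange)) {
    stopifnot(length(residueRange) == 2L)
    if (residueRange[1] > residueRange[2])
      stop("residueRange must satisfy lo <= hi")
    keep <- keep & a$resno >= residueRange[1] & a$resno <= residueRange[2]
  }
  if (!is.null(atomNames)) keep <- keep & a$name %in% atomNames
  out <- a[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write a ModelEnsemble as a multi-model PDB file
#'
#' Emits standard fixed-column PDB with one MODEL/ENDMDL pair per model
#' (also for single-model ensembles, so the dialect is uniform).
#' Coordinates are written at PDB precision (3 decimals), so a
#' read-write-read round trip preserves atom identity exactly and
#' coordinates to 3 decimals.
#'
#' @param ensemble a \linkS4class{ModelEnsemble}.
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
writeModels <- function(ensemble, path) {
  stopifnot(is(ensemble, "ModelEnsemble"))
  validObject(ensemble)
  con <- tryCatch(file(path, "w"),
                  error = function(e) stop("cannot write file: ", path))
  on.exit(close(con))
  tmp <- tempfile(fileext = ".pdb")
  on.exit(unlink(tmp), add = TRUE)
  for (k in seq_along(ensemble@models)) {
    m <- ensemble@models[[k]]
    a <- m@atoms
    if (any(nchar(a$resname) > 3L))
      stop("PDB fixed-column output requires residue names of <= 3 characters")
    n <- nrow(a)
    bio3d::write.pdb(file = tmp, xyz = as.vector(t(coordsMatrix(a))),
                     resno = a$resno, resid = a$resname, eleno = a$serial,
                     elety = a$name, chain = ifelse(nzchar(a$chain),
                                                    a$chain, " "),
                     elesy = a$element, o = rep(1, n), b = rep(0, n),
                     end = FALSE)
    writeLines(sprintf("MODEL     %4d", k), con)
    writeLines(readLines(tmp), con)
    writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}
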