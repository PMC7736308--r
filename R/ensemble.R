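#' Define a domain by chain and residue range
#'
#' A domain is an inclusive author-numbering residue range on one chain, e.g.
#' POTRA1 = residues 24-92 of the BamA chain. Residue numbers at printed
#' domain boundaries that appear in two ranges (e.g. 92 in both POTRA1 and
#' POTRA2) belong to both domains.
#'
#' @param name domain name.
#' @param chain chain identifier.
#' @param residueRange inclusive \code{c(lo, hi)} residue range.
#' @return a \code{DomainDefinition} (list).
#' @export
domainDefinition <- function(name, chain, residueRange) {
  stopifnot(length(residueRange) == 2L)
  if (residueRange[1] > residueRange[2])
    stop("residueRange must satisfy lo <= hi")
  structure(list(name = name, chain = chain,
                 residueRange = as.numeric(residueRange)),
            class = "DomainDefinition")
}

#' Prune an ensemble to its common residue set
#'
#' Restricts every model to the (chain, residue) positions whose trace atom
#' (C-alpha by default) is present in all models, in canonical
#' (chain, residue) order, so per-domain statistics compare like with like
#' across structures determined from different constructs.
#'
#' @param ensemble a \linkS4class{ModelEnsemble} of >= 2 models.
#' @param atomNames trace atom names kept (default \code{"CA"}).
#' @return the pruned \linkS4class{ModelEnsemble}.
#' @export
pruneToCommon <- function(ensemble, atomNames = "CA") {
  stopifnot(is(ensemble, "ModelEnsemble"))
  if (length(ensemble@models) < 2L) stop("need at least 2 models to prune")
  keys <- lapply(ensemble@models, function(m) {
    a <- m@atoms
    unique(paste(a$chain[a$name %in% atomNames],
                 a$resno[a$name %in% atomNames], sep = "\r"))
  })
  common <- Reduce(intersect, keys)
  if (!length(common)) stop("models share no common residues")
  mods <- lapply(ensemble@models, function(m) {
    a <- m@atoms
    a <- a[a$name %in% atomNames &
             paste(a$chain, a$resno, sep = "\r") %in% common, , drop = FALSE]
    a <- a[order(a$chain, a$resno), , drop = FALSE]
    rownames(a) <- NULL
    m@atoms <- a
    m
  })
  new("ModelEnsemble", models = mods, label = ensemble@label)
}

pairedSelection <- function(a, b, selection, atomNames = "CA") {
  selA <- if (is.null(selection)) selectAtoms(a, atomNames = atomNames)
    else selectAtoms(a, chain = selection$chain,
                     residueRange = selection$residueRange,
                     atomNames = atomNames)
  selB <- if (is.null(selection)) selectAtoms(b, atomNames = atomNames)
    else selectAtoms(b, chain = selection$chain,
                     residueRange = selection$residueRange,
                     atomNames = atomNames)
  keyA <- paste(selA$chain, selA$resno, selA$name, sep = "\r")
  keyB <- paste(selB$chain, selB$resno, selB$name, sep = "\r")
  common <- intersect(keyA, keyB)
  list(A = coordsMatrix(selA[match(common, keyA), , drop = FALSE]),
       B = coordsMatrix(selB[match(common, keyB), , drop = FALSE]),
       n = length(common))
}

#' Rigid-body superposition on a selection
#'
#' Least-squares (Kabsch) superposition of \code{mobile} onto
#' \code{reference}, computed on the paired C-alpha atoms of the given
#' selection only; the fitted proper rotation (det = +1) and translation are
#' then applied to all atoms of \code{mobile}.
#'
#' @param mobile,reference \linkS4class{StructureModel} objects.
#' @param selection a \code{\link{domainDefinition}} restricting the fit, or
#'   \code{NULL} to fit on all paired C-alpha atoms.
#' @return list with \code{rotation} (3x3), \code{translation} (3-vector),
#'   \code{rmsd} on the selection after fitting, and \code{model}, the
#'   transformed mobile model.
#' @export
superpose <- function(mobile, reference, selection = NULL) {
  p <- pairedSelection(mobile, reference, selection)
  if (p$n < 3L) stop("selection yields fewer than 3 paired atoms")
  k <- kabsch(p$A, p$B)
  fitted <- sweep(p$A %*% t(k$R), 2, -k$t)
  rmsd <- sqrt(mean(rowSums((fitted - p$B)^2)))
  list(rotation = k$R, translation = k$t, rmsd = rmsd,
       model = transformModel(mobile, k$R, k$t))
}

#' Centre of mass of a domain's C-alpha trace
#'
#' The unweighted centroid of the domain's C-alpha coordinates (all trace
#' atoms have identical mass, so centroid equals centre of mass).
#'
#' @param model a \linkS4class{StructureModel}.
#' @param domain a \code{\link{domainDefinition}}.
#' @return numeric 3-vector (Angstrom).
#' @export
domainCOM <- function(model, domain) {
  sel <- selectAtoms(model, chain = domain$chain,
                     residueRange = domain$residueRange, atomNames = "CA")
  if (!nrow(sel)) stop("domain '", domain$name, "' selects no atoms")
  colMeans(coordsMatrix(sel))
}

#' Domain COM displacement statistics across an ensemble
#'
#' Superposes every model onto the first model of the ensemble using the
#' alignment selection (e.g. the back of a beta-barrel, or the preceding
#' domain), computes each domain's C-alpha centre of mass in the common
#' frame, and reports all pairwise COM distances per domain together with
#' the per-domain maximum. Pairwise distances are invariant to the choice of
#' reference model and to any global rigid transform of the inputs.
#'
#' @param ensemble a (typically pruned) \linkS4class{ModelEnsemble}.
#' @param scheme a \code{\link{domainDefinition}} giving the alignment
#'   reference selection.
#' @param domains list of \code{\link{domainDefinition}} objects.
#' @return a \linkS4class{DisplacementResult}.
#' @export
comDisplacements <- function(ensemble, scheme, domains) {
  stopifnot(is(ensemble, "ModelEnsemble"), length(domains) >= 1L)
  mods <- ensemble@models
  ref <- mods[[1]]
  aligned <- c(list(ref), lapply(mods[-1], function(m)
    superpose(m, ref, scheme)$model))
  dnames <- vapply(domains, `[[`, character(1), "name")
  coms <- lapply(domains, function(d)
    t(vapply(aligned, domainCOM, numeric(3), domain = d)))
  names(coms) <- dnames
  mats <- lapply(coms, function(cm) {
    m <- as.matrix(stats::dist(cm))
    dimnames(m) <- list(modelIds(ensemble), modelIds(ensemble))
    m
  })
  names(mats) <- dnames
  maxima <- vapply(mats, max, numeric(1))
  new("DisplacementResult", domains = dnames, matrices = mats,
      maxima = maxima, coms = coms,
      scheme = sprintf("aligned on %s %s:%g-%g", scheme$name, scheme$chain,
                       scheme$residueRange[1], scheme$residueRange[2]))
}

#' C-alpha RMSD between two models
#'
#' Root-mean-square deviation over paired C-alpha atoms, optionally after
#' optimal rigid superposition on the same selection.
#'
#' @param a,b \linkS4class{StructureModel} objects.
#' @param selection a \code{\link{domainDefinition}} or \code{NULL} for all
#'   paired C-alpha atoms.
#' @param superposeFirst superpose \code{a} onto \code{b} before measuring.
#' @return RMSD in Angstrom.
#' @export
caRMSD <- function(a, b, selection = NULL, superposeFirst = FALSE) {
  if (superposeFirst) a <- superpose(a, b, selection)$model
  p <- pairedSelection(a, b, selection)
  if (p$n == 0L) stop("no paired C-alpha atoms")
  sqrt(mean(rowSums((p$A - p$B)^2)))
}
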