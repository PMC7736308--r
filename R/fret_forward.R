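# Bondi van der Waals radii (Angstrom), keyed by upper-case element symbol.
# Shared by the accessible-volume and contact modules; overridable per call
# and per atom (a 'vdw' atom-table column wins).
.BONDI <- c(H = 1.20, D = 1.20, C = 1.70, N = 1.55, O = 1.52, F = 1.47,
            P = 1.80, S = 1.80, CL = 1.75, BR = 1.85, I = 1.98, SE = 1.90,
            B = 1.92, SI = 2.10, AS = 1.85, K = 2.75, "NA" = 2.27, MG = 1.73,
            ZN = 1.39, FE = 2.00, CA = 2.31, MN = 2.00, CU = 1.40)

#' Bondi van der Waals radii
#'
#' Radii (Angstrom) for the elements of an atom table. An atom-level
#' \code{vdw} column, where present and finite, overrides the element table.
#'
#' @param atoms atom data.frame with an \code{element} column.
#' @param table named radius table to use (default Bondi).
#' @return numeric vector of radii.
#' @export
vdwRadii <- function(atoms, table = .BONDI) {
  el <- toupper(atoms$element)
  r <- table[el]
  if (any(is.na(r))) {
    bad <- unique(el[is.na(r)])
    stop("no van der Waals radius for element(s): ",
         paste(bad, collapse = ", "))
  }
  r <- as.numeric(r)
  if ("vdw" %in% names(atoms)) {
    ov <- atoms$vdw
    r[!is.na(ov)] <- ov[!is.na(ov)]
  }
  r
}

#' Dye parameters for accessible-volume calculation
#'
#' Geometric dye model for the single-sphere accessible-volume
#' approximation: the dye centre may occupy any grid point within
#' \code{linkerLength} of the attachment atom that neither clashes with the
#' protein nor is cut off from the attachment. Defaults are Alexa-488-like
#' (20 Angstrom linker, 4.5 Angstrom linker width, 3.5 Angstrom dye radius);
#' all three are tunable.
#'
#' @param linkerLength maximum dye-centre distance from the attachment atom,
#'   Angstrom.
#' @param linkerWidth linker diameter, Angstrom (the linker path is checked
#'   with probe radius \code{linkerWidth / 2}).
#' @param dyeRadius dye sphere radius, Angstrom.
#' @param chain,resno,atomName attachment site; the default attachment atom
#'   is CB (maleimide dyes attach at the cysteine side chain), with CA as
#'   the glycine fallback.
#' @return a \code{DyeParams} (list).
#' @export
dyeParams <- function(linkerLength = 20, linkerWidth = 4.5, dyeRadius = 3.5,
                      chain = "A", resno = 1, atomName = "CB") {
  if (linkerLength <= 0 || linkerWidth <= 0 || dyeRadius <= 0)
    stop("all dye lengths must be > 0")
  list(linkerLength = linkerLength, linkerWidth = linkerWidth,
       dyeRadius = dyeRadius, chain = chain, resno = resno,
       atomName = atomName)
}

#' Accessible-volume dye cloud
#'
#' Enumerates candidate dye positions on a cubic grid inside the
#' linker-length sphere around the attachment atom and keeps those that (a)
#' do not clash with any non-hydrogen atom (distance >= atom vdW radius +
#' dye radius) and (b) can be reached from the attachment atom along a
#' straight segment sampled at 1 Angstrom steps with probe radius
#' linkerWidth / 2 (single-sphere approximation of flexible-linker
#' accessibility). The attachment atom itself is not an obstacle. Grid
#' enumeration is deterministic, so clouds are reproducible without seeds.
#'
#' @param model a \linkS4class{StructureModel}.
#' @param dye a \code{\link{dyeParams}}.
#' @param gridSpacing grid spacing, Angstrom (default 1).
#' @return a \linkS4class{DyeCloud}; an empty cloud (fully buried site) is
#'   an error.
#' @export
accessibleVolume <- function(model, dye, gridSpacing = 1) {
  att <- selectAtoms(model, chain = dye$chain,
                     residueRange = c(dye$resno, dye$resno),
                     atomNames = dye$atomName)
  if (!nrow(att) && dye$atomName == "CB")
    att <- selectAtoms(model, chain = dye$chain,
                       residueRange = c(dye$resno, dye$resno),
                       atomNames = "CA")
  if (!nrow(att)) stop("attachment atom not found")
  a0 <- as.numeric(coordsMatrix(att)[1, ])
  prot <- model@atoms
  prot <- prot[toupper(prot$element) != "H", , drop = FALSE]
  self <- prot$chain == att$chain[1] & prot$resno == att$resno[1] &
    prot$name == att$name[1]
  prot <- prot[!self, , drop = FALSE]
  L <- dye$linkerLength
  off <- seq(-floor(L / gridSpacing), floor(L / gridSpacing)) * gridSpacing
  cand <- as.matrix(expand.grid(x = off, y = off, z = off))
  cand <- cand[rowSums(cand^2) <= L^2, , drop = FALSE]
  cand <- sweep(cand, 2, -a0)     # grid centred on the attachment atom
  if (nrow(prot)) {
    pr <- coordsMatrix(prot)
    rad <- vdwRadii(prot)
    clash <- function(points, probe) {
      # TRUE where a point is within (vdw + probe) of any protein atom
      hit <- rep(FALSE, nrow(points))
      for (j in seq_len(nrow(pr))) {
        d2 <- (points[, 1] - pr[j, 1])^2 + (points[, 2] - pr[j, 2])^2 +
          (points[, 3] - pr[j, 3])^2
        hit <- hit | d2 < (rad[j] + probe)^2
      }
      hit
    }
    cand <- cand[!clash(cand, dye$dyeRadius), , drop = FALSE]
    if (nrow(cand)) {
      reach <- vapply(seq_len(nrow(cand)), function(i) {
        p <- cand[i, ]
        v <- p - a0
        len <- sqrt(sum(v^2))
        if (len < 1e-9) return(TRUE)
        nstep <- max(1L, ceiling(len))  # ~1 A sampling
        fr <- seq_len(nstep - 1L) / nstep
        if (!length(fr)) return(TRUE)
        seg <- outer(fr, v) + matrix(a0, length(fr), 3, byrow = TRUE)
        !any(clash(seg, dye$linkerWidth / 2))
      }, logical(1))
      cand <- cand[reach, , drop = FALSE]
    }
  }
  if (!nrow(cand)) stop("accessible volume is empty (buried attachment site)")
  new("DyeCloud", points = unname(cand), attachment = a0, params = dye)
}

#' Interdye distance distribution between two clouds
#'
#' Normalised histogram of distances over all inter-cloud point pairs
#' (uniform weights); when the full cross product exceeds \code{maxPairs}
#' (default 1e6), that many pairs are sampled uniformly with a fixed seed so
#' results are reproducible.
#'
#' @param cloudA,cloudB \linkS4class{DyeCloud} objects (non-empty).
#' @param binWidth histogram bin width, Angstrom (default 1).
#' @param maxPairs cap on evaluated pairs.
#' @param seed seed for pair subsampling.
#' @return data.frame with bin \code{lo}, \code{hi}, \code{mid} and
#'   probability \code{p} (summing to 1).
#' @export
distanceDistribution <- function(cloudA, cloudB, binWidth = 1,
                                 maxPairs = 1e6, seed = 1) {
  A <- cloudPoints(cloudA); B <- cloudPoints(cloudB)
  if (!nrow(A) || !nrow(B)) stop("clouds must be non-empty")
  nPairs <- as.double(nrow(A)) * nrow(B)
  if (nPairs <= maxPairs) {
    d2 <- outer(rowSums(A^2), rowSums(B^2), "+") - 2 * A %*% t(B)
    d <- sqrt(pmax(as.vector(d2), 0))
  } else {
    d <- withSeed(seed, {
      ia <- sample.int(nrow(A), maxPairs, replace = TRUE)
      ib <- sample.int(nrow(B), maxPairs, replace = TRUE)
      sqrt(rowSums((A[ia, , drop = FALSE] - B[ib, , drop = FALSE])^2))
    })
  }
  # bins centred on multiples of binWidth, so a delta distribution at an
  # integer distance reports that distance as its bin midpoint exactly
  nbin <- floor(max(d) / binWidth + 0.5) + 1
  breaks <- binWidth * seq(0, nbin) - binWidth / 2
  h <- hist(d, breaks = breaks, plot = FALSE)
  data.frame(lo = breaks[-length(breaks)], hi = breaks[-1],
             mid = binWidth * seq(0, nbin - 1), p = h$counts / length(d))
}

#' Predicted FRET efficiency from a distance distribution
#'
#' Converts a normalised interdye distance histogram into the predicted mean
#' transfer efficiency, mean_E = sum p(R) E(R, R0) over bin centres, and
#' least-squares fits the implied E distribution with a single Gaussian
#' (reported as mu, sigma). A degenerate (single-bin) distribution returns
#' sigma = 0 with mu at the corresponding efficiency.
#'
#' @param distances data.frame from \code{\link{distanceDistribution}} (or
#'   any with columns \code{mid} and \code{p} summing to 1).
#' @param R0 Forster radius, Angstrom (default 60).
#' @return list with \code{meanE}, Gaussian \code{mu} and \code{sigma}, and
#'   the per-bin efficiencies \code{E} with weights \code{p}.
#' @export
predictEfret <- function(distances, R0 = 60) {
  if (!nrow(distances)) stop("empty distance histogram")
  p <- distances$p
  if (abs(sum(p) - 1) > 1e-6) stop("distance histogram must be normalised")
  E <- efretForster(distances$mid, R0)
  meanE <- sum(p * E)
  used <- p > 0
  muW <- sum(p * E)
  sdW <- sqrt(max(sum(p * (E - muW)^2), 0))
  if (sum(used) < 3L || sdW < 1e-9) {
    fit <- c(mu = muW, sigma = sdW)
  } else {
    # density of E on a fixed grid, then least-squares single Gaussian
    grid <- seq(0, 1, by = 0.005)
    bw <- max(sdW / 2, 0.005)
    dens <- colSums(p[used] * stats::dnorm(outer(E[used], grid, "-"),
                                           sd = bw))
    obj <- function(th) {
      mu <- th[1]; sig <- exp(th[2]); A <- exp(th[3])
      sum((A * stats::dnorm(grid, mu, sig) - dens)^2)
    }
    opt <- stats::optim(c(muW, log(max(sdW, 1e-3)), 0), obj,
                        method = "Nelder-Mead",
                        control = list(maxit = 2000, reltol = 1e-12))
    fit <- c(mu = opt$par[1], sigma = exp(opt$par[2]))
  }
  list(meanE = meanE, mu = unname(fit["mu"]), sigma = unname(fit["sigma"]),
       E = E, p = p, R0 = R0)
}
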