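#' Forster transfer efficiency
#'
#' Evaluates E = 1 / (1 + (R/R0)^6), the FRET efficiency at interdye
#' distance R for Forster radius R0.
#'
#' @param R interdye distance(s), Angstrom (>= 0).
#' @param R0 Forster radius, Angstrom (> 0; 60 for the Alexa488/DyLight594
#'   pair used throughout this package).
#' @return efficiency in [0, 1], vectorised over \code{R}.
#' @export
efretForster <- function(R, R0 = 60) {
  if (any(R < 0) || any(!is.finite(R))) stop("R must be finite and >= 0")
  if (length(R0) != 1L || !is.finite(R0) || R0 <= 0) stop("R0 must be > 0")
  1 / (1 + (R / R0)^6)
}

#' Read / write a photon table
#'
#' Photon tables are tab-delimited text with a header and columns
#' \code{timestamp_us} (non-decreasing), \code{channel} (\code{donor} /
#' \code{acceptor} detection channel) and \code{excitation} (\code{donor} /
#' \code{acceptor} excitation slot).
#'
#' @param path file path.
#' @param photons data.frame to write.
#' @return \code{readPhotons} returns the photon data.frame;
#'   \code{writePhotons} returns \code{path} invisibly.
#' @export
readPhotons <- function(path) {
  if (!file.exists(path)) stop("cannot read file: ", path)
  p <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("timestamp_us", "channel", "excitation")
  if (!all(need %in% names(p)))
    stop("photon table must have columns: ", paste(need, collapse = ", "))
  if (is.unsorted(p$timestamp_us)) stop("timestamps must be non-decreasing")
  p
}

#' @rdname readPhotons
#' @export
writePhotons <- function(photons, path) {
  utils::write.table(photons, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Sliding-window burst detection
#'
#' All-photon sliding-window search: a photon belongs to a burst region when
#' it starts a run of \code{windowM} photons spanning at most \code{windowT}
#' microseconds; contiguous qualifying photons are merged into bursts and
#' bursts with fewer than \code{minPhotons} photons in total are discarded.
#' Per burst, photon counts are tallied by detection channel and excitation
#' slot: \code{FDD} (donor channel, donor excitation), \code{FDA} (acceptor
#' channel, donor excitation) and \code{FAA} (acceptor channel, acceptor
#' excitation), and the raw proximity ratio \code{Eraw = FDA/(FDA+FDD)} is
#' recorded.
#'
#' @param photons photon data.frame (see \code{\link{readPhotons}}).
#' @param minPhotons lower threshold on photons per burst (default 20).
#' @param windowM photons per search window (default 10).
#' @param windowT window span in microseconds (default 500).
#' @return a \linkS4class{BurstTable} (empty stream gives zero rows).
#' @export
detectBursts <- function(photons, minPhotons = 20, windowM = 10,
                         windowT = 500) {
  t <- photons$timestamp_us
  n <- length(t)
  params <- list(minPhotons = minPhotons, windowM = windowM,
                 windowT = windowT)
  empty <- data.frame(start = numeric(0), end = numeric(0),
                      nPhotons = integer(0), FDD = integer(0),
                      FDA = integer(0), FAA = integer(0), Eraw = numeric(0))
  if (n < windowM)
    return(new("BurstTable", bursts = empty, params = params))
  if (is.unsorted(t)) stop("timestamps must be non-decreasing")
  m <- as.integer(windowM)
  starts <- which(t[m:n] - t[seq_len(n - m + 1L)] <= windowT)
  if (!length(starts))
    return(new("BurstTable", bursts = empty, params = params))
  # mark photons covered by any qualifying window via a difference array
  cover <- integer(n + 1L)
  cover[starts] <- cover[starts] + 1L
  cover[starts + m] <- cover[starts + m] - 1L
  inBurst <- cumsum(cover[seq_len(n)]) > 0L
  r <- rle(inBurst)
  hi <- cumsum(r$lengths)
  lo <- hi - r$lengths + 1L
  runs <- which(r$values & r$lengths >= minPhotons)
  if (!length(runs))
    return(new("BurstTable", bursts = empty, params = params))
  dex <- photons$excitation == "donor"
  acc <- photons$channel == "acceptor"
  tally <- function(flag) {
    cs <- c(0L, cumsum(flag))
    cs[hi[runs] + 1L] - cs[lo[runs]]
  }
  out <- data.frame(
    start = t[lo[runs]], end = t[hi[runs]],
    nPhotons = r$lengths[runs],
    FDD = tally(dex & !acc),
    FDA = tally(dex & acc),
    FAA = tally(!dex & acc))
  out$Eraw <- ifelse(out$FDA + out$FDD > 0,
                     out$FDA / (out$FDA + out$FDD), NA_real_)
  new("BurstTable", bursts = out, params = params)
}

#' Apply ALEX corrections to burst counts
#'
#' Standard accurate-FRET corrections for alternating-laser excitation:
#' donor leakage into the acceptor channel and acceptor direct excitation
#' are subtracted from the acceptor signal,
#' \code{Fcorr = FDA - leakage*FDD - directExcitation*FAA}, and the
#' gamma-corrected efficiency and stoichiometry are
#' \code{Ecorr = Fcorr / (Fcorr + gamma*FDD)} and
#' \code{S = (Fcorr + gamma*FDD) / (Fcorr + gamma*FDD + FAA)}. Bursts with a
#' zero denominator are flagged invalid and excluded downstream. With
#' \code{gamma = 1}, \code{leakage = 0} and \code{directExcitation = 0},
#' \code{Ecorr} reduces to the raw proximity ratio.
#'
#' @param burstTable a \linkS4class{BurstTable} from
#'   \code{\link{detectBursts}}.
#' @param gamma detection-efficiency correction factor (> 0).
#' @param leakage donor leakage fraction (>= 0).
#' @param directExcitation acceptor direct-excitation fraction (>= 0).
#' @return the \linkS4class{BurstTable} with \code{Ecorr}, \code{S} and
#'   \code{valid} columns added.
#' @export
correctBursts <- function(burstTable, gamma = 1, leakage = 0,
                          directExcitation = 0) {
  stopifnot(is(burstTable, "BurstTable"))
  if (gamma <= 0) stop("gamma must be > 0")
  if (leakage < 0 || directExcitation < 0)
    stop("correction factors must be >= 0")
  b <- burstTable@bursts
  fcorr <- b$FDA - leakage * b$FDD - directExcitation * b$FAA
  den <- fcorr + gamma * b$FDD
  tot <- den + b$FAA
  b$Ecorr <- ifelse(den != 0, fcorr / den, NA_real_)
  b$S <- ifelse(tot != 0, den / tot, NA_real_)
  b$valid <- den != 0 & tot != 0
  burstTable@bursts <- b
  burstTable@params <- c(burstTable@params,
                         list(gamma = gamma, leakage = leakage,
                              directExcitation = directExcitation))
  burstTable
}

#' Stoichiometry and acceptor-photon burst filters
#'
#' Keeps bursts whose stoichiometry lies in the closed \code{sRange}
#' (default 0.25-0.75, retaining double-labelled molecules) and that contain
#' at least \code{minAcceptorDuringDonor} acceptor-channel photons during
#' donor excitation (default 3). Invalid (zero-denominator) bursts are
#' always removed.
#'
#' @param burstTable a corrected \linkS4class{BurstTable}.
#' @param sRange closed stoichiometry interval.
#' @param minAcceptorDuringDonor lower threshold on \code{FDA}.
#' @return the filtered \linkS4class{BurstTable}.
#' @export
filterBursts <- function(burstTable, sRange = c(0.25, 0.75),
                         minAcceptorDuringDonor = 3) {
  stopifnot(is(burstTable, "BurstTable"))
  b <- burstTable@bursts
  if (!"S" %in% names(b)) stop("bursts must be corrected first")
  keep <- b$valid & !is.na(b$S) & b$S >= sRange[1] & b$S <= sRange[2] &
    b$FDA >= minAcceptorDuringDonor
  burstTable@bursts <- b[keep, , drop = FALSE]
  rownames(burstTable@bursts) <- NULL
  burstTable@params <- c(burstTable@params,
                         list(sRange = sRange,
                              minAcceptorDuringDonor = minAcceptorDuringDonor))
  burstTable
}

#' Burst-time autocorrelation
#'
#' Histogram of all pairwise forward differences between burst times,
#' normalised by the expectation for a homogeneous Poisson process with the
#' same mean rate over the same observation span, so uncorrelated bursts
#' give g(t) ~ 1 and recurring molecules give g(t) > 1 at short lags. For n
#' uniform times on (0, T), the expected number of ordered pairs with
#' difference in [l, u) is n(n-1) ((u - l) T - (u^2 - l^2)/2) / T^2.
#'
#' @param burstTimes burst occurrence times, milliseconds.
#' @param lagBins lag bin edges in milliseconds (default 0-100 ms in 2 ms
#'   bins).
#' @param duration observation span in ms (default spanned range of
#'   \code{burstTimes}).
#' @return data.frame with bin edges, midpoints, pair counts, Poisson
#'   expectation and \code{g}.
#' @export
burstACF <- function(burstTimes, lagBins = seq(0, 100, by = 2),
                     duration = NULL) {
  t <- sort(as.numeric(burstTimes))
  n <- length(t)
  if (n < 2L) stop("need at least 2 bursts")
  if (is.null(duration)) duration <- max(t) - min(t)
  t <- t - min(t)
  # cumulative ordered-pair count with forward difference <= tau
  cumPairs <- function(tau)
    sum(findInterval(t + tau, t) - seq_len(n))
  edges <- lagBins
  cp <- vapply(edges, cumPairs, numeric(1))
  counts <- diff(cp)
  lo <- edges[-length(edges)]; hi <- edges[-1]
  expected <- n * (n - 1) *
    ((hi - lo) * duration - (hi^2 - lo^2) / 2) / duration^2
  data.frame(lagLo = lo, lagHi = hi, lagMid = (lo + hi) / 2,
             count = counts, expected = expected, g = counts / expected)
}

#' Same-molecule probability from the burst autocorrelation
#'
#' P_same(t) = 1 - 1/g(t), clamped to [0, 1] (finite-sample g can dip below
#' 1, which would otherwise give a negative probability).
#'
#' @param g autocorrelation value(s), > 0.
#' @return probability in [0, 1], vectorised.
#' @export
pSame <- function(g) {
  if (any(!is.finite(g)) || any(g <= 0)) stop("g must be finite and > 0")
  pmin(pmax(1 - 1 / g, 0), 1)
}

#' Consecutive recurrence burst pairs
#'
#' Extracts all pairs of consecutive filtered bursts whose inter-burst gap
#' (start of the later minus end of the earlier burst) is below
#' \code{dtMaxMs}; each pair contributes the corrected efficiencies
#' (E0, E1) of the earlier and later burst. Optionally, pairs can be
#' restricted to lag bins whose same-molecule probability (from a
#' \code{\link{burstACF}} result) reaches \code{pSameMin}.
#'
#' @param burstTable a corrected, filtered \linkS4class{BurstTable}.
#' @param dtMaxMs maximum inter-burst gap in milliseconds (default 30).
#' @param acf optional \code{\link{burstACF}} result for the same bursts.
#' @param pSameMin optional same-molecule probability threshold (requires
#'   \code{acf}); off by default.
#' @return data.frame with columns \code{E0}, \code{E1}, \code{dt} (ms) and
#'   the row indices of the two bursts. May be empty.
#' @export
recurrencePairs <- function(burstTable, dtMaxMs = 30, acf = NULL,
                            pSameMin = NULL) {
  stopifnot(is(burstTable, "BurstTable"))
  b <- burstTable@bursts
  if (!"Ecorr" %in% names(b)) stop("bursts must be corrected first")
  if (nrow(b) < 2L)
    return(data.frame(E0 = numeric(0), E1 = numeric(0), dt = numeric(0),
                      i0 = integer(0), i1 = integer(0)))
  ord <- order(b$start)
  b <- b[ord, , drop = FALSE]
  gapMs <- (b$start[-1] - b$end[-nrow(b)]) / 1000
  sel <- which(gapMs < dtMaxMs)
  pairs <- data.frame(E0 = b$Ecorr[sel], E1 = b$Ecorr[sel + 1L],
                      dt = gapMs[sel], i0 = ord[sel], i1 = ord[sel + 1L])
  if (!is.null(pSameMin)) {
    if (is.null(acf)) stop("pSameMin requires an acf result")
    bin <- findInterval(pairs$dt, acf$lagLo)
    ok <- bin >= 1 & bin <= nrow(acf)
    p <- rep(0, nrow(pairs))
    p[ok] <- pSame(pmax(acf$g[bin[ok]], 1e-12))
    pairs <- pairs[p >= pSameMin, , drop = FALSE]
  }
  rownames(pairs) <- NULL
  pairs
}

#' 2D kernel density of recurrence pairs
#'
#' Gaussian-kernel 2D density of the (E0, E1) pairs, evaluated on a regular
#' grid over the unit square. The kernel is an isotropic bivariate normal
#' with standard deviation \code{bandwidth} in both E dimensions.
#'
#' @param pairs data.frame from \code{\link{recurrencePairs}} (>= 1 pair).
#' @param bandwidth Gaussian kernel standard deviation in E units
#'   (default 0.012).
#' @param gridStep grid spacing over [0, 1] in both axes (default 0.002).
#' @return list with grid coordinates \code{x} (E0), \code{y} (E1) and the
#'   density matrix \code{z} (rows index E0).
#' @export
pairDensity <- function(pairs, bandwidth = 0.012, gridStep = 0.002) {
  if (!nrow(pairs)) stop("need at least one pair")
  g <- seq(0, 1, by = gridStep)
  kx <- stats::dnorm(outer(g, pairs$E0, "-"), sd = bandwidth)
  ky <- stats::dnorm(outer(g, pairs$E1, "-"), sd = bandwidth)
  z <- (kx %*% t(ky)) / nrow(pairs)
  list(x = g, y = g, z = z, bandwidth = bandwidth)
}
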