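# Synthetic-data generators. Every generator is a pure function of its spec
# (including the seed): the same spec gives bit-identical output, and each
# returns a groundTruth record sufficient to compute the expected output of
# the downstream analysis without rerunning the generator.

asSurface <- function(s) {
  if (is.function(s)) return(s)
  force(s); function(x, y) rep_len(as.numeric(s), length(x))
}

#' Largest-remainder apportionment of composition counts
#'
#' Deterministically converts label ratios into integer counts that sum
#' exactly to \code{n}: floors of the proportional shares, remaining units
#' assigned by decreasing fractional remainder (ties by label order).
#'
#' @param weights named non-negative ratios (e.g.
#'   \code{c(PVPE = 70, PVPG = 25, PVCL = 5)}).
#' @param n total count to apportion.
#' @return named integer vector summing to \code{n}.
#' @export
largestRemainder <- function(weights, n) {
  stopifnot(all(weights >= 0), sum(weights) > 0, n >= 0)
  share <- weights / sum(weights) * n
  base <- floor(share)
  left <- n - sum(base)
  if (left > 0) {
    ord <- order(-(share - base), seq_along(share))
    base[ord[seq_len(left)]] <- base[ord[seq_len(left)]] + 1
  }
  stats::setNames(as.integer(base), names(weights))
}

# 3-character PDB residue code for a (possibly longer) lipid label.
lipidCode <- function(label) {
  ifelse(nchar(label) <= 3L, label,
         paste0(substr(label, 1, 1),
                substr(label, nchar(label) - 1L, nchar(label))))
}

#' Bilayer specification for the nanodisc generator
#'
#' Describes a disc-shaped bilayer patch by its two leaflet surfaces
#' z = f(x, y) and z = g(x, y) (f > g inside the disc), the disc radius, the
#' number of lipids per leaflet, the headgroup composition ratios, and the
#' Gaussian positional noise applied to each phosphate. Defaults emulate an
#' MSP1D1-scale nanodisc (97 Angstrom diameter, phosphate planes at +/-20
#' Angstrom, i.e. 40 Angstrom thickness) with the E. coli polar-lipid-like
#' composition PVPE:PVPG:PVCL = 70:25:5.
#'
#' @param discRadius disc radius, Angstrom.
#' @param nLipidsPerLeaflet lipids per leaflet (>= 3).
#' @param surfaceUpper,surfaceLower leaflet surfaces: a constant z or a
#'   function (x, y) -> z, Angstrom.
#' @param composition named label ratios.
#' @param positionalNoiseSd isotropic Gaussian noise sd per phosphate,
#'   Angstrom.
#' @param seed RNG seed.
#' @return a \code{BilayerSpec} (list).
#' @export
bilayerSpec <- function(discRadius = 48.5, nLipidsPerLeaflet = 80,
                        surfaceUpper = 20, surfaceLower = -20,
                        composition = c(PVPE = 70, PVPG = 25, PVCL = 5),
                        positionalNoiseSd = 1, seed = 1) {
  if (nLipidsPerLeaflet < 3) stop("need at least 3 lipids per leaflet")
  if (discRadius <= 0) stop("discRadius must be > 0")
  spec <- list(discRadius = discRadius,
               nLipidsPerLeaflet = as.integer(nLipidsPerLeaflet),
               surfaceUpper = asSurface(surfaceUpper),
               surfaceLower = asSurface(surfaceLower),
               composition = composition,
               positionalNoiseSd = positionalNoiseSd, seed = seed)
  # sanity-check f > g on a radial sample
  xs <- seq(-discRadius, discRadius, length.out = 7)
  gr <- expand.grid(x = xs, y = xs)
  inside <- gr$x^2 + gr$y^2 <= discRadius^2
  if (any(spec$surfaceUpper(gr$x[inside], gr$y[inside]) <=
            spec$surfaceLower(gr$x[inside], gr$y[inside])))
    stop("surfaceUpper must lie above surfaceLower inside the disc")
  spec
}

#' Scaffold-belt specification
#'
#' A helical-belt C-alpha trace: \code{nResidues} pseudo-residues
#' (poly-alanine) evenly spaced on a circle of \code{radius} at height
#' \code{zCenter}, displaced out of plane by \code{deviationProfile}
#' (a function of angular position in radians, returning Angstrom offsets).
#'
#' @param radius belt radius, Angstrom.
#' @param nResidues residues in the belt (>= 10).
#' @param zCenter belt height, Angstrom.
#' @param deviationProfile function(theta) -> out-of-plane offset, or a
#'   constant.
#' @param seed RNG seed (reserved; the default belt is deterministic).
#' @return a \code{BeltSpec} (list).
#' @export
beltSpec <- function(radius = 53, nResidues = 90, zCenter = 10,
                     deviationProfile = 0, seed = 1) {
  if (radius <= 0) stop("radius must be > 0")
  if (nResidues < 10) stop("belt needs at least 10 residues")
  prof <- if (is.function(deviationProfile)) deviationProfile
          else {force(deviationProfile)
                function(theta) rep_len(as.numeric(deviationProfile),
                                        length(theta))}
  list(radius = radius, nResidues = as.integer(nResidues), zCenter = zCenter,
       deviationProfile = prof, seed = seed)
}

#' Generate nanodisc trajectory frames with known ground truth
#'
#' Builds \code{nFrames} coordinate snapshots of a synthetic nanodisc: one
#' phosphorus pseudo-atom per lipid placed uniformly in the disc on its
#' leaflet surface plus isotropic Gaussian noise (upper leaflet chain U,
#' lower chain V), and two scaffold-belt C-alpha chains (M and N) following
#' their deviation profiles. Headgroup labels are apportioned by largest
#' remainder; the 3-character PDB residue codes for long labels are recorded
#' in the ground truth. Lipid in-plane positions are redrawn every frame
#' (diffusion surrogate); belts are deterministic.
#'
#' @param spec a \code{\link{bilayerSpec}}.
#' @param belts list of two \code{\link{beltSpec}}s (upper, lower).
#' @param nFrames number of frames (>= 1).
#' @return list with \code{frames} (a \linkS4class{TrajectoryFrames}) and
#'   \code{groundTruth} (true thickness field, label counts, belt deviation
#'   per residue, generating spec).
#' @export
makeNanodiscFrames <- function(spec,
                               belts = list(beltSpec(zCenter = 10),
                                            beltSpec(zCenter = -10)),
                               nFrames = 10) {
  stopifnot(nFrames >= 1, length(belts) == 2L)
  nl <- spec$nLipidsPerLeaflet
  counts <- largestRemainder(spec$composition, nl)
  labels <- rep(names(counts), counts)
  codes <- lipidCode(labels)
  beltAtoms <- function(bs, chain, serial0) {
    th <- 2 * pi * (seq_len(bs$nResidues) - 1L) / bs$nResidues
    xyz <- cbind(bs$radius * cos(th), bs$radius * sin(th),
                 bs$zCenter + bs$deviationProfile(th))
    atomTable(serial0 + seq_len(bs$nResidues), "CA", "C", "ALA", chain,
              seq_len(bs$nResidues), xyz)
  }
  makeFrame <- function(k) {
    lipXY <- function() {
      r <- spec$discRadius * sqrt(stats::runif(nl))
      a <- stats::runif(nl, 0, 2 * pi)
      cbind(r * cos(a), r * sin(a))
    }
    up <- lipXY(); lo <- lipXY()
    noise <- function() if (spec$positionalNoiseSd > 0)
      matrix(stats::rnorm(3 * nl, sd = spec$positionalNoiseSd), ncol = 3)
      else matrix(0, nl, 3)
    upXYZ <- cbind(up, spec$surfaceUpper(up[, 1], up[, 2])) + noise()
    loXYZ <- cbind(lo, spec$surfaceLower(lo[, 1], lo[, 2])) + noise()
    atoms <- rbind(
      atomTable(seq_len(nl), "P", "P", codes, "U", seq_len(nl), upXYZ),
      atomTable(nl + seq_len(nl), "P", "P", codes, "V", seq_len(nl), loXYZ),
      beltAtoms(belts[[1]], "M", 2L * nl),
      beltAtoms(belts[[2]], "N", 2L * nl + belts[[1]]$nResidues))
    newModel(k, atoms)
  }
  mods <- withSeed(spec$seed, lapply(seq_len(nFrames), makeFrame))
  th1 <- 2 * pi * (seq_len(belts[[1]]$nResidues) - 1L) / belts[[1]]$nResidues
  th2 <- 2 * pi * (seq_len(belts[[2]]$nResidues) - 1L) / belts[[2]]$nResidues
  gt <- list(
    thickness = function(x, y) spec$surfaceUpper(x, y) - spec$surfaceLower(x, y),
    labelCounts = counts,
    labelCodes = stats::setNames(lipidCode(names(counts)), names(counts)),
    beltDeviation = list(M = belts[[1]]$deviationProfile(th1),
                         N = belts[[2]]$deviationProfile(th2)),
    spec = spec, belts = belts, nFrames = nFrames)
  list(frames = new("TrajectoryFrames", models = mods,
                    label = "synthetic nanodisc",
                    frameStrideNote = "independently generated frames"),
       groundTruth = gt)
}

#' Generate an articulated multi-domain ensemble with known COM truth
#'
#' Builds a chain of rigid pseudo-domains (C-alpha-only helical segments
#' connected head-to-tail on chain A) and an ensemble of \code{nModels}
#' copies in which each inter-domain hinge is rotated by a per-model
#' (axis, angle) about the junction atom, applied cumulatively from the
#' first hinge outward. Domain 1 is never moved, so the generated
#' coordinates are natively in the "aligned on domain 1" frame. The ground
#' truth records, by exact affine bookkeeping (no superposition), every
#' domain COM in every model under every "align on domain d" scheme, and
#' the corresponding pairwise COM displacement matrices and maxima.
#'
#' @param nModels number of models (>= 1).
#' @param domainSizes residue counts per domain (>= 2 domains, each >= 1).
#' @param hingeRotations per-model list: element m is a list with one
#'   \code{list(axis =, angle =)} (degrees) per hinge, or \code{NULL} for no
#'   rotation. If missing, random axes and N(0, sd = 5 degrees) angles are
#'   drawn.
#' @param seed RNG seed (used only when \code{hingeRotations} is missing).
#' @return list with \code{ensemble} (a \linkS4class{ModelEnsemble}),
#'   \code{domains} (the \code{\link{domainDefinition}} list) and
#'   \code{groundTruth} (\code{coms[[scheme]][[domain]]}: model x 3 COM
#'   matrices; \code{matrices[[scheme]][[domain]]}; \code{maxima}).
#' @export
makeArticulatedEnsemble <- function(nModels = 16, domainSizes = c(30, 25, 25),
                                    hingeRotations = NULL, seed = 1) {
  nd <- length(domainSizes)
  if (nd < 2L) stop("need at least 2 domains")
  if (any(domainSizes < 1L)) stop("every domain needs at least 1 residue")
  if (is.null(hingeRotations)) {
    hingeRotations <- withSeed(seed, lapply(seq_len(nModels), function(m) {
      lapply(seq_len(nd - 1L), function(h) {
        ax <- stats::rnorm(3)
        list(axis = ax / sqrt(sum(ax^2)), angle = stats::rnorm(1, sd = 5))
      })
    }))
  }
  stopifnot(length(hingeRotations) == nModels)
  # base chain: helical C-alpha trace, 1.5 A rise per residue along x
  totRes <- sum(domainSizes)
  i <- seq_len(totRes)
  base <- cbind(1.5 * i, 2 * cos(i * 100 * pi / 180),
                2 * sin(i * 100 * pi / 180))
  hiRes <- cumsum(domainSizes)
  loRes <- hiRes - domainSizes + 1L
  domIdx <- lapply(seq_len(nd), function(d) loRes[d]:hiRes[d])
  domains <- lapply(seq_len(nd), function(d)
    domainDefinition(paste0("D", d), "A", c(loRes[d], hiRes[d])))
  baseCOM <- lapply(domIdx, function(ix) colMeans(base[ix, , drop = FALSE]))

  buildModel <- function(m) {
    rots <- hingeRotations[[m]]
    xyz <- base
    # affine transform (R, t) accumulated per domain
    Ts <- lapply(seq_len(nd), function(d) list(R = diag(3), t = c(0, 0, 0)))
    for (h in seq_len(nd - 1L)) {
      r <- rots[[h]]
      if (is.null(r) || r$angle == 0) next
      R <- rotationMatrix(r$axis, r$angle)
      pivot <- xyz[hiRes[h], ]            # junction atom, current position
      move <- (hiRes[h] + 1L):totRes
      xyz[move, ] <- sweep(sweep(xyz[move, , drop = FALSE], 2, pivot) %*%
                             t(R), 2, -pivot)
      t0 <- pivot - R %*% pivot
      for (d in (h + 1L):nd) {
        Ts[[d]] <- list(R = R %*% Ts[[d]]$R,
                        t = as.numeric(R %*% Ts[[d]]$t + t0))
      }
    }
    list(model = newModel(m, atomTable(i, "CA", "C", "ALA", "A", i, xyz)),
         Ts = Ts)
  }
  built <- lapply(seq_len(nModels), buildModel)
  mods <- lapply(built, `[[`, "model")

  applyT <- function(T, v) as.numeric(T$R %*% v + T$t)
  invT <- function(T) list(R = t(T$R), t = as.numeric(-t(T$R) %*% T$t))
  schemes <- paste0("align_D", seq_len(nd))
  coms <- lapply(seq_len(nd), function(d) {
    lapply(seq_len(nd), function(j) {
      t(vapply(seq_len(nModels), function(m) {
        Td <- built[[m]]$Ts[[d]]; Tj <- built[[m]]$Ts[[j]]
        applyT(invT(Td), applyT(Tj, baseCOM[[j]]))
      }, numeric(3)))
    })
  })
  names(coms) <- schemes
  for (d in seq_len(nd)) names(coms[[d]]) <- paste0("D", seq_len(nd))
  matrices <- lapply(coms, function(sc) lapply(sc, function(cm)
    as.matrix(stats::dist(cm))))
  maxima <- lapply(matrices, function(sc) vapply(sc, max, numeric(1)))
  list(ensemble = new("ModelEnsemble", models = mods,
                      label = "articulated synthetic ensemble"),
       domains = domains,
       groundTruth = list(coms = coms, matrices = matrices, maxima = maxima,
                          baseCOM = baseCOM, domainSizes = domainSizes))
}

#' Photon-stream specification for the ALEX simulator
#'
#' Conditions of the emulated alternating-laser-excitation measurement: the
#' discrete FRET states a molecule can occupy (efficiency and mean dwell
#' time), the transition matrix drawn from when a jump occurs, burst and
#' background rates, the laser alternation period and duty cycle (40
#' microseconds / 40 percent, as in the measurement this emulates), the
#' recurrence model (probability of a second burst from the same molecule
#' and the gap range), and the correction factors baked into the emitted
#' counts.
#'
#' @param states data.frame with columns \code{E} (true transfer efficiency
#'   in [0, 1)) and \code{dwellMs} (mean dwell time, ms).
#' @param transitionMatrix row-stochastic matrix drawn from on a jump
#'   (self-entries are zeroed and rows renormalised); default uniform over
#'   the other states.
#' @param burstRate primary-burst rate, bursts per second.
#' @param photonsPerBurstMean mean photons per burst (Poisson). The default
#'   is a bright-burst regime in which the shot-noise width of per-burst E
#'   (about 0.016 at E = 0.2) is small enough that states 0.05 apart remain
#'   separable by the 0.012-bandwidth density analysis.
#' @param backgroundRateD,backgroundRateA background photon rates (Hz) in
#'   the donor and acceptor channels.
#' @param alternationPeriodUs laser alternation period, microseconds.
#' @param dutyCycle fraction of the period each laser is on (in (0, 0.5]).
#' @param recurrenceProb probability that a molecule re-enters the confocal
#'   volume and emits a paired second burst.
#' @param recurrenceGapRangeMs gap range (ms) between the end of a burst and
#'   the start of its recurrence, drawn uniformly.
#' @param burstDurationMeanMs mean burst duration (exponential), ms.
#' @param durationS total stream duration, seconds.
#' @param gamma,leakage,directExcitation correction factors applied in
#'   reverse when emitting photons, so that \code{\link{correctBursts}} with
#'   the same factors recovers the true state efficiencies.
#' @param seed RNG seed.
#' @return a \code{PhotonStreamSpec} (list).
#' @export
photonStreamSpec <- function(states = data.frame(E = c(0.13, 0.20, 0.25),
                                                 dwellMs = c(10, 10, 10)),
                             transitionMatrix = NULL,
                             burstRate = 5, photonsPerBurstMean = 1500,
                             backgroundRateD = 1000, backgroundRateA = 1000,
                             alternationPeriodUs = 40, dutyCycle = 0.4,
                             recurrenceProb = 0.35,
                             recurrenceGapRangeMs = c(1, 25),
                             burstDurationMeanMs = 1,
                             durationS = 60,
                             gamma = 1, leakage = 0, directExcitation = 0,
                             seed = 1) {
  ns <- nrow(states)
  if (is.null(transitionMatrix)) {
    transitionMatrix <- matrix(1 / max(ns - 1, 1), ns, ns)
    diag(transitionMatrix) <- 0
    if (ns == 1L) transitionMatrix <- matrix(1, 1, 1)
  }
  if (any(abs(rowSums(transitionMatrix) - 1) > 1e-9))
    stop("transition matrix rows must sum to 1")
  if (dutyCycle <= 0 || dutyCycle > 0.5)
    stop("dutyCycle must be in (0, 0.5]")
  if (durationS <= 0) stop("duration must be positive")
  if (any(states$E < 0 | states$E >= 1))
    stop("state efficiencies must be in [0, 1)")
  list(states = states, transitionMatrix = transitionMatrix,
       burstRate = burstRate, photonsPerBurstMean = photonsPerBurstMean,
       backgroundRateD = backgroundRateD, backgroundRateA = backgroundRateA,
       alternationPeriodUs = alternationPeriodUs, dutyCycle = dutyCycle,
       recurrenceProb = recurrenceProb,
       recurrenceGapRangeMs = recurrenceGapRangeMs,
       burstDurationMeanMs = burstDurationMeanMs, durationS = durationS,
       gamma = gamma, leakage = leakage,
       directExcitation = directExcitation, seed = seed)
}

# Acceptor-channel probability during donor excitation that makes the
# forward photon model the exact inverse of the correctBursts algebra (with
# expected acceptor-/donor-excitation count ratio rho).
.alexPA <- function(E, gamma, leakage, direct, rho) {
  q <- leakage + gamma * E / (1 - E)
  (q + direct * rho) / (1 + q)
}

#' Simulate an alternating-laser-excitation photon stream
#'
#' Emits a time-sorted photon table (timestamp_us, channel, excitation) from
#' molecules interconverting between discrete FRET states, plus background.
#' Primary bursts arrive as a Poisson process; each burst draws a state
#' (stationary occupancy), an exponential duration and a Poisson photon
#' count, splits photons between donor- and acceptor-excitation slots, and
#' draws acceptor-channel detections during donor excitation with the
#' probability that makes \code{\link{correctBursts}} (with the same gamma /
#' leakage / direct-excitation factors) recover the state efficiency. With
#' probability \code{recurrenceProb} the molecule re-enters and emits a
#' paired burst after a uniform gap; it keeps its state unless a jump is
#' drawn from the dwell time over the gap, in which case the new state comes
#' from the transition matrix. The ground truth records every burst's
#' interval, true state and recurrence pairing.
#'
#' @param spec a \code{\link{photonStreamSpec}}.
#' @return list with \code{photons} (data.frame) and \code{groundTruth}
#'   (bursts data.frame with \code{start}, \code{end} (us), \code{state},
#'   \code{E}, \code{molecule}, \code{isRecurrence}, \code{pairedWith}).
#' @export
simulateALEXPhotons <- function(spec) {
  withSeed(spec$seed, {
    P <- spec$alternationPeriodUs
    slotW <- spec$dutyCycle * P
    durUs <- spec$durationS * 1e6
    ns <- nrow(spec$states)
    # stationary occupancy of the jump chain (uniform dwell weighting)
    occ <- rep(1 / ns, ns)
    if (ns > 1L) {
      ev <- eigen(t(spec$transitionMatrix))
      k <- which.min(abs(ev$values - 1))
      v <- abs(Re(ev$vectors[, k]))
      occ <- v / sum(v)
    }
    nPrim <- stats::rpois(1, spec$burstRate * spec$durationS)
    prim <- sort(stats::runif(nPrim, 0, durUs))
    st <- sample.int(ns, nPrim, replace = TRUE, prob = occ)
    dur <- stats::rexp(nPrim, rate = 1 / (spec$burstDurationMeanMs * 1e3))
    bursts <- data.frame(start = prim, durUs = dur, state = st,
                         molecule = seq_len(nPrim),
                         isRecurrence = logical(nPrim),
                         pairedWith = rep(NA_integer_, nPrim))
    rec <- stats::runif(nPrim) < spec$recurrenceProb
    if (any(rec)) {
      i <- which(rec)
      gap <- stats::runif(length(i), spec$recurrenceGapRangeMs[1],
                          spec$recurrenceGapRangeMs[2]) * 1e3
      start2 <- bursts$start[i] + bursts$durUs[i] + gap
      dwell <- spec$states$dwellMs[bursts$state[i]] * 1e3
      jump <- stats::runif(length(i)) < (1 - exp(-gap / dwell))
      st2 <- bursts$state[i]
      if (any(jump) && ns > 1L) {
        Tm <- spec$transitionMatrix
        diag(Tm) <- 0
        rs <- rowSums(Tm)
        for (j in which(jump)) {
          row <- Tm[st2[j], ]
          if (rs[st2[j]] > 0)
            st2[j] <- sample.int(ns, 1, prob = row / rs[st2[j]])
        }
      }
      dur2 <- stats::rexp(length(i),
                          rate = 1 / (spec$burstDurationMeanMs * 1e3))
      keep <- start2 + dur2 < durUs
      if (any(keep)) {
        add <- data.frame(start = start2[keep], durUs = dur2[keep],
                          state = st2[keep], molecule = i[keep],
                          isRecurrence = TRUE, pairedWith = i[keep])
        bursts <- rbind(bursts, add)
      }
    }
    bursts <- bursts[order(bursts$start), , drop = FALSE]
    rownames(bursts) <- NULL
    nb <- nrow(bursts)

    # photons per burst
    snap <- function(tRaw, slotStart) {
      # place each photon in the active slot of its alternation period
      floor(tRaw / P) * P + slotStart + stats::runif(length(tRaw), 0, slotW)
    }
    photonChunks <- vector("list", nb + 2L)
    if (nb > 0) {
      nPh <- stats::rpois(nb, spec$photonsPerBurstMean)
      pA <- .alexPA(spec$states$E[bursts$state], spec$gamma, spec$leakage,
                    spec$directExcitation, rho = 1)
      for (k in seq_len(nb)) {
        if (nPh[k] == 0L) next
        tRaw <- bursts$start[k] + stats::runif(nPh[k], 0, bursts$durUs[k])
        dex <- stats::runif(nPh[k]) < 0.5
        tt <- numeric(nPh[k])
        tt[dex] <- snap(tRaw[dex], 0)
        tt[!dex] <- snap(tRaw[!dex], P / 2)
        chan <- ifelse(dex,
                       ifelse(stats::runif(nPh[k]) < pA[k], "acceptor",
                              "donor"),
                       "acceptor")
        photonChunks[[k]] <- data.frame(
          timestamp_us = tt, channel = chan,
          excitation = ifelse(dex, "donor", "acceptor"))
      }
    }
    bg <- function(rate, channel) {
      nBg <- stats::rpois(1, rate * spec$durationS)
      if (nBg == 0L) return(NULL)
      tRaw <- stats::runif(nBg, 0, durUs)
      dex <- stats::runif(nBg) < 0.5
      tt <- numeric(nBg)
      tt[dex] <- snap(tRaw[dex], 0)
      tt[!dex] <- snap(tRaw[!dex], P / 2)
      data.frame(timestamp_us = tt, channel = channel,
                 excitation = ifelse(dex, "donor", "acceptor"))
    }
    photonChunks[[nb + 1L]] <- bg(spec$backgroundRateD, "donor")
    photonChunks[[nb + 2L]] <- bg(spec$backgroundRateA, "acceptor")
    photons <- do.call(rbind, photonChunks[!vapply(photonChunks, is.null,
                                                   logical(1))])
    if (is.null(photons))
      photons <- data.frame(timestamp_us = numeric(0),
                            channel = character(0), excitation = character(0))
    photons <- photons[order(photons$timestamp_us), , drop = FALSE]
    rownames(photons) <- NULL
    gt <- data.frame(start = bursts$start,
                     end = bursts$start + bursts$durUs,
                     state = bursts$state,
                     E = spec$states$E[bursts$state],
                     molecule = bursts$molecule,
                     isRecurrence = bursts$isRecurrence,
                     pairedWith = bursts$pairedWith)
    list(photons = photons, groundTruth = gt)
  })
}

#' Pseudo-atom fixture for dye accessible-volume tests
#'
#' A minimal \linkS4class{StructureModel} with two labelled attachment atoms
#' (CB of CYS residues 1 and 2 on chain A) and optional obstacle
#' pseudo-atoms whose effective van der Waals radii are carried in an extra
#' \code{vdw} atom column (respected by \code{\link{accessibleVolume}}).
#'
#' @param attachmentA,attachmentB distinct 3-vector attachment positions.
#' @param obstacles list of \code{list(center =, radius =)} pseudo-atoms, or
#'   an n x 3 matrix of centres (default radius 1.7).
#' @return a \linkS4class{StructureModel}.
#' @export
makeDyeFixture <- function(attachmentA, attachmentB, obstacles = list()) {
  if (all(attachmentA == attachmentB))
    stop("attachment points must be distinct")
  if (is.matrix(obstacles))
    obstacles <- lapply(seq_len(nrow(obstacles)), function(i)
      list(center = obstacles[i, ], radius = 1.7))
  nObs <- length(obstacles)
  xyz <- rbind(attachmentA, attachmentB,
               if (nObs) t(vapply(obstacles, function(o)
                 as.numeric(o$center), numeric(3))))
  atoms <- atomTable(seq_len(2L + nObs),
                     c("CB", "CB", rep("O", nObs)),
                     c("C", "C", rep("O", nObs)),
                     c("CYS", "CYS", rep("OBS", nObs)),
                     "A", seq_len(2L + nObs), xyz)
  atoms$vdw <- c(NA_real_, NA_real_,
                 if (nObs) vapply(obstacles, function(o)
                   as.numeric(o$radius), numeric(1)))
  newModel("dye-fixture", atoms)
}
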