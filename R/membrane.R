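#' Total-least-squares plane fit
#'
#' Fits the plane minimising the sum of squared orthogonal distances to the
#' points (via SVD of the centred coordinates). The normal is oriented
#' towards the +z hemisphere; when its z component is zero the first
#' non-zero of (x, y) is made positive.
#'
#' @param points numeric n x 3 matrix (n >= 3, non-collinear).
#' @return list with \code{point} (the centroid) and unit \code{normal}.
#' @export
fitPlane <- function(points) {
  P <- as.matrix(points)
  if (nrow(P) < 3L) stop("plane fit needs at least 3 points")
  ctr <- colMeans(P)
  Pc <- sweep(P, 2, ctr)
  s <- svd(Pc, nu = 0)
  if (s$d[2] <= max(s$d[1], 1) * 1e-9) stop("points are collinear")
  n <- s$v[, 3]
  if (n[3] < 0) n <- -n
  else if (n[3] == 0) {
    if (n[1] < 0 || (n[1] == 0 && n[2] < 0)) n <- -n
  }
  list(point = ctr, normal = n / sqrt(sum(n^2)))
}

signedDistance <- function(points, plane) {
  as.numeric(sweep(as.matrix(points), 2, plane$point) %*% plane$normal)
}

#' Assign lipids to leaflets and fit the bilayer central plane
#'
#' A plane is first fitted to all phosphate positions and each lipid assigned
#' to the upper or lower leaflet by the sign of its distance from this plane.
#' Individual planes are then fitted to each leaflet and averaged (point and
#' renormalised normal) to give a more accurate central plane; assignments
#' are re-checked against the central plane and the refinement iterated until
#' stable (at most 10 iterations).
#'
#' @param phosphates numeric n x 3 matrix of phosphate positions (n >= 6,
#'   spanning both sides of the global fit plane).
#' @return list with \code{upper} and \code{lower} (lipid index vectors) and
#'   \code{plane}, the central plane.
#' @export
assignLeaflets <- function(phosphates) {
  P <- as.matrix(phosphates)
  if (nrow(P) < 6L) stop("need at least 6 lipids to assign leaflets")
  plane <- fitPlane(P)
  up <- signedDistance(P, plane) >= 0
  if (all(up) || !any(up)) stop("all lipids on one side of the fit plane")
  for (i in seq_len(10L)) {
    if (sum(up) < 3L || sum(!up) < 3L)
      stop("a leaflet has fewer than 3 lipids")
    pu <- fitPlane(P[up, , drop = FALSE])
    pl <- fitPlane(P[!up, , drop = FALSE])
    # both leaflet normals already point into the +z hemisphere
    n <- pu$normal + pl$normal
    central <- list(point = (pu$point + pl$point) / 2,
                    normal = n / sqrt(sum(n^2)))
    up2 <- signedDistance(P, central) >= 0
    if (all(up2) || !any(up2)) stop("leaflet refinement emptied one leaflet")
    stable <- identical(up2, up)
    up <- up2
    plane <- central
    if (stable) break
  }
  # a single noisy sheet splits about its own fit plane; require genuinely
  # separated leaflets (bilayers are tens of Angstrom apart)
  s <- signedDistance(P, plane)
  sep <- mean(s[up]) - mean(s[!up])
  if (sep < 2)
    stop("lipids do not form two separated leaflets (all on one side?)")
  list(upper = which(up), lower = which(!up), plane = plane)
}

# Deterministic, content-anchored in-plane coordinate system: principal axes
# of the projected points, each axis sign-fixed by its third central moment,
# so the basis co-rotates with the data under rigid transforms.
planeBasis <- function(points, plane) {
  P <- as.matrix(points)
  s <- signedDistance(P, plane)
  proj <- P - outer(s, plane$normal)
  origin <- colMeans(proj)
  C <- sweep(proj, 2, origin)
  ev <- eigen(crossprod(C), symmetric = TRUE)
  e1 <- ev$vectors[, 1]; e2 <- ev$vectors[, 2]
  m1 <- sum((C %*% e1)^3); m2 <- sum((C %*% e2)^3)
  if (m1 < 0) e1 <- -e1
  if (m2 < 0) e2 <- -e2
  list(origin = origin, e1 = e1, e2 = e2)
}

inPlaneCoords <- function(points, plane, basis) {
  P <- as.matrix(points)
  s <- signedDistance(P, plane)
  proj <- P - outer(s, plane$normal)
  C <- sweep(proj, 2, basis$origin)
  cbind(C %*% basis$e1, C %*% basis$e2)
}

# Mask of grid cells inside the convex hull of the projected phosphates,
# eroded inward by one grid spacing ("inside the nanodisc").
discMask <- function(uv, gx, gy, spacing) {
  h <- grDevices::chull(uv)
  hull <- uv[h, , drop = FALSE]
  ctr <- colMeans(hull)
  cells <- cbind(rep(gx, times = length(gy)), rep(gy, each = length(gx)))
  keep <- rep(TRUE, nrow(cells))
  nh <- nrow(hull)
  for (i in seq_len(nh)) {
    a <- hull[i, ]; b <- hull[if (i == nh) 1L else i + 1L, ]
    e <- b - a
    n <- c(-e[2], e[1])
    n <- n / sqrt(sum(n^2))
    if (sum((ctr - a) * n) < 0) n <- -n   # inward normal
    keep <- keep & (sweep(cells[, 1:2, drop = FALSE], 2, a) %*% n) >= spacing
  }
  matrix(keep, nrow = length(gx))
}

# Mean height of the k nearest (in-plane) headgroups of one leaflet at each
# masked cell. Ties in distance are broken by lipid index.
knnHeights <- function(cellUV, leafUV, heights, k) {
  apply(cellUV, 1L, function(p) {
    d2 <- (leafUV[, 1] - p[1])^2 + (leafUV[, 2] - p[2])^2
    ord <- order(d2, seq_along(d2))[seq_len(k)]
    mean(heights[ord])
  })
}

phosphateCoords <- function(frame) {
  a <- selectAtoms(frame, atomNames = NULL)
  coordsMatrix(a[a$element == "P", , drop = FALSE])
}

# Project a reference in-plane basis onto this frame's central plane
# (Gram-Schmidt), keeping cell indexing consistent across frames.
carryBasis <- function(refBasis, points, plane) {
  n <- plane$normal
  e1 <- refBasis$e1 - sum(refBasis$e1 * n) * n
  if (sqrt(sum(e1^2)) < 1e-6)
    stop("reference basis is degenerate on this frame's plane")
  e1 <- e1 / sqrt(sum(e1^2))
  e2 <- refBasis$e2 - sum(refBasis$e2 * n) * n - sum(refBasis$e2 * e1) * e1
  if (sqrt(sum(e2^2)) < 1e-6)
    stop("reference basis is degenerate on this frame's plane")
  e2 <- e2 / sqrt(sum(e2^2))
  s <- signedDistance(points, plane)
  proj <- as.matrix(points) - outer(s, n)
  list(origin = colMeans(proj), e1 = e1, e2 = e2)
}

# Core per-frame thickness evaluation; grid = list(x, y, mask, spacing) or
# NULL to build the grid from this frame. refBasis carries the first
# frame's in-plane axes so grid cells index the same bilayer locations.
.thicknessFrame <- function(P, spacing, k, grid = NULL, refBasis = NULL) {
  lf <- assignLeaflets(P)
  basis <- if (is.null(refBasis)) planeBasis(P, lf$plane)
           else carryBasis(refBasis, P, lf$plane)
  uv <- inPlaneCoords(P, lf$plane, basis)
  h <- abs(signedDistance(P, lf$plane))
  if (length(lf$upper) < k || length(lf$lower) < k)
    stop("a leaflet has fewer than k lipids")
  if (is.null(grid)) {
    gx <- seq(floor(min(uv[, 1])), ceiling(max(uv[, 1])), by = spacing)
    gy <- seq(floor(min(uv[, 2])), ceiling(max(uv[, 2])), by = spacing)
    grid <- list(x = gx, y = gy, mask = discMask(uv, gx, gy, spacing),
                 spacing = spacing)
  }
  cells <- cbind(rep(grid$x, times = length(grid$y)),
                 rep(grid$y, each = length(grid$x)))
  sel <- as.vector(grid$mask)
  th <- rep(NA_real_, nrow(cells))
  cellUV <- cells[sel, , drop = FALSE]
  hu <- knnHeights(cellUV, uv[lf$upper, , drop = FALSE], h[lf$upper], k)
  hl <- knnHeights(cellUV, uv[lf$lower, , drop = FALSE], h[lf$lower], k)
  th[sel] <- hu + hl
  list(grid = grid, thickness = matrix(th, nrow = length(grid$x)),
       leaflets = lf, basis = basis)
}

#' Per-frame bilayer thickness map
#'
#' Computes the bilayer thickness of a single coordinate frame on a square
#' grid in the frame's central-plane coordinate system. Each phosphate is
#' projected onto the central plane and its height taken as the absolute
#' orthogonal distance; the height of a grid cell is the mean height of the
#' \code{kNeighbours} nearest projected headgroups (2D nearest, per leaflet),
#' and thickness is the sum of the upper- and lower-leaflet heights. Only
#' cells inside the nanodisc (convex hull of the projected phosphates,
#' eroded by one spacing) are evaluated.
#'
#' @param frame a \linkS4class{StructureModel} (phosphorus atoms are used as
#'   the lipid positions) or an n x 3 matrix of phosphate coordinates.
#' @param spacing grid spacing in Angstrom (default 1).
#' @param kNeighbours number of nearest headgroups averaged per leaflet
#'   (default 3).
#' @return list with \code{x}, \code{y} (cell-centre coordinates),
#'   \code{mask}, \code{thickness} (matrix, NA outside the mask), and the
#'   leaflet assignment.
#' @export
thicknessMap <- function(frame, spacing = 1, kNeighbours = 3) {
  P <- if (is(frame, "StructureModel")) phosphateCoords(frame)
       else as.matrix(frame)
  if (nrow(P) == 0L) stop("no phosphate atoms found in frame")
  r <- .thicknessFrame(P, spacing, kNeighbours)
  list(x = r$grid$x, y = r$grid$y, mask = r$grid$mask,
       thickness = r$thickness, leaflets = r$leaflets)
}

#' Aggregate thickness statistics over trajectory frames
#'
#' Evaluates the per-frame thickness map of every frame and reports the
#' per-cell mean and population standard deviation across frames. Each frame
#' is analysed in its own best-fit central plane; the in-plane axes of the
#' first frame are carried onto every later frame's plane (projected and
#' re-orthonormalised), so cells are indexed identically on the grid defined
#' by the first frame (same cell-centre coordinates and in-disc mask).
#'
#' @param frames a \linkS4class{TrajectoryFrames} or
#'   \linkS4class{ModelEnsemble} of >= 2 frames with identical atoms, or a
#'   list of phosphate coordinate matrices.
#' @param spacing grid spacing in Angstrom.
#' @param kNeighbours nearest headgroups averaged per leaflet.
#' @param keepFrames store the per-frame thickness matrices in the result.
#' @return a \linkS4class{ThicknessGrid}.
#' @export
aggregateThickness <- function(frames, spacing = 1, kNeighbours = 3,
                               keepFrames = TRUE) {
  if (is(frames, "ModelEnsemble")) {
    keys <- lapply(frames@models, function(m)
      paste(m@atoms$chain, m@atoms$resno, m@atoms$name, sep = "|"))
    if (length(unique(vapply(keys, paste, character(1), collapse = "\r"))) != 1L)
      stop("frames must share identical atom identity")
    mats <- lapply(frames@models, phosphateCoords)
  } else mats <- lapply(frames, as.matrix)
  if (length(mats) < 2L) stop("need at least 2 frames to aggregate")
  first <- .thicknessFrame(mats[[1]], spacing, kNeighbours)
  grid <- first$grid
  perFrame <- vector("list", length(mats))
  perFrame[[1]] <- first$thickness
  for (i in seq_along(mats)[-1])
    perFrame[[i]] <- .thicknessFrame(mats[[i]], spacing, kNeighbours,
                                     grid = grid,
                                     refBasis = first$basis)$thickness
  arr <- simplify2array(perFrame)
  mu <- apply(arr, c(1, 2), mean)
  sdm <- sqrt(apply(arr, c(1, 2), function(v) mean((v - mean(v))^2)))
  new("ThicknessGrid", x = grid$x, y = grid$y, spacing = spacing,
      mask = grid$mask, mean = mu, sd = sdm,
      perFrame = if (keepFrames) perFrame else list(),
      nFrames = length(mats))
}

#' Scaffold-belt deviation-from-planarity profile
#'
#' For each frame a plane is fitted to the belt's C-alpha atoms and each
#' C-alpha is projected onto the plane; the Euclidean distance between the
#' C-alpha (x, y, z) and its projection (x_p, y_p, z_p) is accumulated per
#' residue over all frames, and the profile reports log10 of the per-residue
#' sum. A per-residue sum below 1e-12 Angstrom (a perfectly planar belt) is
#' floored at 1e-12 before the logarithm, giving the sentinel score -12.
#'
#' @param frames a \linkS4class{TrajectoryFrames}/\linkS4class{ModelEnsemble}
#'   (with \code{chain} naming the belt), or a list of per-frame n x 3
#'   C-alpha coordinate matrices (rows = residues, same order every frame).
#' @param chain belt chain identifier (required for ensemble input).
#' @param atomName trace atom name, default \code{"CA"}.
#' @return a \linkS4class{PlanarityProfile}.
#' @export
planarityProfile <- function(frames, chain = NULL, atomName = "CA") {
  if (is(frames, "ModelEnsemble")) {
    if (is.null(chain)) stop("chain is required for ensemble input")
    sel <- lapply(frames@models, selectAtoms, chain = chain,
                  atomNames = atomName)
    resno <- sel[[1]]$resno
    mats <- lapply(sel, coordsMatrix)
    ch <- chain
  } else {
    mats <- lapply(frames, as.matrix)
    resno <- seq_len(nrow(mats[[1]]))
    ch <- if (is.null(chain)) "" else chain
  }
  if (!length(mats)) stop("need at least one frame")
  nres <- nrow(mats[[1]])
  if (nres < 3L) stop("belt needs at least 3 residues")
  total <- numeric(nres)
  for (M in mats) {
    if (nrow(M) != nres) stop("belt residue count differs between frames")
    pl <- fitPlane(M)
    total <- total + abs(signedDistance(M, pl))
  }
  new("PlanarityProfile", resno = as.integer(resno),
      score = log10(pmax(total, 1e-12)),
      nFrames = length(mats), chain = ch)
}
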