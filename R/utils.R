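# Internal geometry and RNG helpers shared across modules.

# Evaluate `code` under a private RNG state seeded with `seed`; the caller's
# RNG state is untouched.
withSeed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed))
    stop("seed must be a single finite number")
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

#' Rotation matrix about an arbitrary axis
#'
#' Rodrigues rotation matrix for a right-handed rotation of \code{angle}
#' degrees about \code{axis} (through the origin).
#'
#' @param axis numeric 3-vector (need not be unit length).
#' @param angle rotation angle in degrees.
#' @return 3x3 rotation matrix \code{R}, to be applied as \code{R \%*\% x}.
#' @export
rotationMatrix <- function(axis, angle) {
  stopifnot(length(axis) == 3L, all(is.finite(axis)), is.finite(angle))
  n <- sqrt(sum(axis^2))
  if (n < 1e-12) stop("rotation axis must be non-zero")
  u <- axis / n
  th <- angle * pi / 180
  K <- matrix(c(0, u[3], -u[2], -u[3], 0, u[1], u[2], -u[1], 0), 3, 3)
  diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
}

# n x 3 coordinate matrix of an atom table / StructureModel.
coordsMatrix <- function(x) {
  a <- if (is(x, "StructureModel")) x@atoms else x
  as.matrix(a[, c("x", "y", "z"), drop = FALSE])
}

setCoords <- function(model, xyz) {
  model@atoms$x <- xyz[, 1]
  model@atoms$y <- xyz[, 2]
  model@atoms$z <- xyz[, 3]
  model
}

# Apply rigid transform y = R x + t to every atom of a model.
transformModel <- function(model, R, t = c(0, 0, 0)) {
  xyz <- coordsMatrix(model)
  setCoords(model, sweep(xyz %*% t(R), 2, -t))
}

# Kabsch least-squares superposition: rotation R and translation t with
# det(R) = +1 minimising sum |R x_i + t - y_i|^2.
kabsch <- function(X, Y) {
  stopifnot(nrow(X) == nrow(Y), nrow(X) >= 3L)
  cx <- colMeans(X); cy <- colMeans(Y)
  Xc <- sweep(X, 2, cx); Yc <- sweep(Y, 2, cy)
  s <- svd(crossprod(Xc, Yc))
  d <- sign(det(s$v %*% t(s$u)))
  if (d == 0) d <- 1
  R <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  list(R = R, t = as.numeric(cy - R %*% cx))
}

newModel <- function(modelId, atoms) {
  rownames(atoms) <- NULL
  new("StructureModel", modelId = as.character(modelId), atoms = atoms)
}

atomTable <- function(serial, name, element, resname, chain, resno, xyz) {
  data.frame(serial = as.integer(serial), name = name, element = element,
             resname = resname, chain = chain, resno = as.integer(resno),
             x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
             stringsAsFactors = FALSE)
}
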