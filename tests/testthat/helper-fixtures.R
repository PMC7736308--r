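# Fixture builders and independent oracles used across the test files.

# Minimal StructureModel from a coordinate matrix (CA trace on one chain).
caModel <- function(xyz, modelId = "1", chain = "A",
                    resno = seq_len(nrow(xyz))) {
  atoms <- data.frame(serial = seq_len(nrow(xyz)), name = "CA",
                      element = "C", resname = "ALA", chain = chain,
                      resno = as.integer(resno),
                      x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
                      stringsAsFactors = FALSE)
  new("StructureModel", modelId = modelId, atoms = atoms)
}

# n random CA positions under a fixed seed.
randomXYZ <- function(n, seed, scale = 20) {
  set.seed(seed)
  matrix(runif(3 * n, -scale, scale), ncol = 3)
}

# Independent quaternion (Horn) superposition oracle: rotation mapping X
# onto Y by the largest eigenvector of the 4x4 key matrix.
hornRotation <- function(X, Y) {
  Xc <- sweep(X, 2, colMeans(X))
  Yc <- sweep(Y, 2, colMeans(Y))
  S <- t(Xc) %*% Yc
  key <- matrix(0, 4, 4)
  key[1, 1] <- S[1, 1] + S[2, 2] + S[3, 3]
  key[1, 2] <- key[2, 1] <- S[2, 3] - S[3, 2]
  key[1, 3] <- key[3, 1] <- S[3, 1] - S[1, 3]
  key[1, 4] <- key[4, 1] <- S[1, 2] - S[2, 1]
  key[2, 2] <- S[1, 1] - S[2, 2] - S[3, 3]
  key[2, 3] <- key[3, 2] <- S[1, 2] + S[2, 1]
  key[2, 4] <- key[4, 2] <- S[3, 1] + S[1, 3]
  key[3, 3] <- -S[1, 1] + S[2, 2] - S[3, 3]
  key[3, 4] <- key[4, 3] <- S[2, 3] + S[3, 2]
  key[4, 4] <- -S[1, 1] - S[2, 2] + S[3, 3]
  q <- eigen(key, symmetric = TRUE)$vectors[, 1]
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(w^2 + x^2 - y^2 - z^2, 2 * (x * y + w * z), 2 * (x * z - w * y),
           2 * (x * y - w * z), w^2 - x^2 + y^2 - z^2, 2 * (y * z + w * x),
           2 * (x * z + w * y), 2 * (y * z - w * x),
           w^2 - x^2 - y^2 + z^2), 3, 3)
}

hornRMSD <- function(X, Y) {
  R <- hornRotation(X, Y)
  Xr <- sweep(X, 2, colMeans(X)) %*% t(R)
  Yc <- sweep(Y, 2, colMeans(Y))
  sqrt(mean(rowSums((Xr - Yc)^2)))
}

# Brute-force k-nearest-neighbour mean-height oracle in 2D.
bruteKnnHeight <- function(cell, uv, heights, k) {
  d2 <- (uv[, 1] - cell[1])^2 + (uv[, 2] - cell[2])^2
  mean(heights[order(d2, seq_along(d2))[seq_len(k)]])
}

# Direct double-loop Gaussian KDE oracle on a coarse grid.
bruteKDE <- function(pairs, xs, ys, bw) {
  z <- matrix(0, length(xs), length(ys))
  for (i in seq_along(xs))
    for (j in seq_along(ys))
      z[i, j] <- mean(dnorm(xs[i] - pairs$E0, sd = bw) *
                        dnorm(ys[j] - pairs$E1, sd = bw))
  z
}

# Uniform random rigid transform under a fixed seed.
randomRigid <- function(seed) {
  set.seed(seed)
  ax <- rnorm(3)
  list(R = memdyn::rotationMatrix(ax, runif(1, 10, 170)),
       t = runif(3, -30, 30))
}

applyRigidXYZ <- function(xyz, rt) sweep(xyz %*% t(rt$R), 2, -rt$t)

applyRigidModel <- function(model, rt) {
  a <- atoms(model)
  xyz <- applyRigidXYZ(as.matrix(a[, c("x", "y", "z")]), rt)
  a$x <- xyz[, 1]; a$y <- xyz[, 2]; a$z <- xyz[, 3]
  new("StructureModel", modelId = model@modelId, atoms = a)
}

setModelId <- function(model, id) {
  model@modelId <- as.character(id)
  model
}

# Distance from 2D points to a ray from the origin along unit vector u.
distToRay <- function(x, y, u) {
  along <- x * u[1] + y * u[2]
  perp <- abs(x * u[2] - y * u[1])
  ifelse(along >= 0, perp, sqrt(x^2 + y^2))
}

applyRigidEnsemble <- function(ens, rt) {
  new(class(ens), models = lapply(models(ens), applyRigidModel, rt = rt),
      label = ens@label)
}
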