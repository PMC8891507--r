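# Geometry fixtures are built in code: analytic curves with known arc
# length / chord, and small planted bundle sets for clustering tests.

# densely sampled circular arc in the xy-plane
arcStreamline <- function(radius, fraction = 0.5, n = 2000, center = c(0, 0, 0),
                          startAngle = 0) {
  th <- seq(startAngle, startAngle + 2 * pi * fraction, length.out = n)
  cbind(center[1] + radius * cos(th), center[2] + radius * sin(th),
        center[3])
}

lineStreamline <- function(from, to, n = 20) {
  t <- seq(0, 1, length.out = n)
  outer(1 - t, from) + outer(t, to)
}

# bundle of nearly parallel n-point lines around a given offset
parallelBundle <- function(center, nStreamlines, spread = 1, n = 20,
                           length = 60, seed = 1) {
  set.seed(seed)
  lapply(seq_len(nStreamlines), function(i) {
    off <- rnorm(3, sd = spread)
    s <- lineStreamline(center + off + c(0, 0, -length / 2),
                        center + off + c(0, 0, length / 2), n)
    if (i %% 2 == 0) s[n:1, , drop = FALSE] else s
  })
}

# k planted parallel bundles separated along x; returns streamlines + labels
plantedBundles <- function(k = 3, perBundle = 20, separation = 40, spread = 1,
                           n = 20, seed = 1) {
  sl <- list(); labels <- integer()
  for (b in seq_len(k)) {
    bun <- parallelBundle(c((b - 1) * separation, 0, 0), perBundle,
                          spread = spread, n = n, seed = seed + b)
    sl <- c(sl, bun)
    labels <- c(labels, rep(b - 1L, perBundle))
  }
  list(streamlines = sl, labels = labels)
}

# sparse density map built directly from a voxel->fraction table
handDensityMap <- function(fractions, nStreamlines, refDim = c(4L, 4L, 4L),
                           refAffine = diag(4)) {
  idx <- as.integer(names(fractions))
  new("TractDensityMap", indices = idx, fractions = unname(fractions),
      refDim = as.integer(refDim), refAffine = refAffine,
      nStreamlines = as.integer(nStreamlines))
}

rigidTransform <- function(s, angle = 0.7, axis = c(0, 0, 1),
                           translation = c(5, -3, 2)) {
  axis <- axis / sqrt(sum(axis^2))
  K <- matrix(c(0, -axis[3], axis[2], axis[3], 0, -axis[1],
                -axis[2], axis[1], 0), 3, 3, byrow = TRUE)
  R <- diag(3) + sin(angle) * K + (1 - cos(angle)) * (K %*% K)
  sweep(s %*% t(R), 2, translation, `+`)
}
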