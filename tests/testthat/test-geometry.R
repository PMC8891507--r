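test_that("arc length and endpoint distance match analytic values", {
  expect_equal(arcLength(rbind(c(0, 0, 0), c(3, 4, 0))), 5)
  expect_equal(endpointDistance(rbind(c(0, 0, 0), c(3, 4, 0))), 5)

  # closed polyline: positive length, zero chord
  loop <- rbind(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0), c(0, 0, 0))
  expect_gt(arcLength(loop), 0)
  expect_equal(endpointDistance(loop), 0)

  semi <- arcStreamline(15, 0.5)
  expect_equal(arcLength(semi), 15 * pi, tolerance = 1e-3)
  expect_equal(endpointDistance(semi), 30, tolerance = 1e-6)

  # chord never exceeds arc length
  for (seed in 1:5) {
    set.seed(seed)
    s <- matrix(cumsum(rnorm(30)), 10, 3)
    expect_lte(endpointDistance(s), arcLength(s))
  }
})

test_that("arc length and endpoint distance are rigid-transform invariant", {
  set.seed(42)
  s <- matrix(cumsum(rnorm(60)), 20, 3)
  st <- rigidTransform(s)
  expect_equal(arcLength(st), arcLength(s), tolerance = 1e-9)
  expect_equal(endpointDistance(st), endpointDistance(s), tolerance = 1e-9)
})

test_that("resampling yields equispaced points with preserved endpoints", {
  # straight segment: exact positions
  r <- resampleStreamline(rbind(c(0, 0, 0), c(19, 0, 0)), 20)
  expect_equal(r, cbind(0:19, 0, 0), tolerance = 1e-12)

  # idempotence on already-equispaced input
  expect_equal(resampleStreamline(r, 20), r, tolerance = 1e-9)

  # quarter circle against a dense arc-length re-integration oracle
  q <- arcStreamline(10, 0.25, n = 5000)
  L <- arcLength(q)
  r <- resampleStreamline(q, 20)
  expect_equal(r[1, ], q[1, ], tolerance = 1e-6)
  expect_equal(r[20, ], q[nrow(q), ], tolerance = 1e-6)
  spacing <- sqrt(rowSums(diff(r)^2))
  # equal spacing to machine-level relative tolerance; each chord equals the
  # arc step L/19 up to the chord-vs-arc curvature gap (~delta^2/24)
  expect_equal(spacing, rep(mean(spacing), 19), tolerance = 1e-6)
  expect_equal(mean(spacing), L / 19, tolerance = 1e-3)
  # oracle: positions from a 1e5-subdivision arc-length table
  dense <- arcStreamline(10, 0.25, n = 1e5 + 1)
  cum <- c(0, cumsum(sqrt(rowSums(diff(dense)^2))))
  tgt <- seq(0, max(cum), length.out = 20)
  idx <- findInterval(tgt, cum, rightmost.closed = TRUE)
  w <- (tgt - cum[idx]) / pmax(cum[idx + 1] - cum[idx], 1e-300)
  oracle <- dense[idx, ] * (1 - w) + dense[pmin(idx + 1, nrow(dense)), ] * w
  expect_equal(r, oracle, tolerance = 1e-4)

  # resampling never lengthens a polyline (chord shortening)
  expect_lte(arcLength(resampleStreamline(q, 7)), arcLength(q))

  expect_error(resampleStreamline(rbind(c(1, 1, 1), c(1, 1, 1)), 10),
               "degenerate")
  expect_error(resampleStreamline(rbind(c(1, 1, 1), c(1, 1, 1)), 10, index = 7),
               "7")
})

test_that("MDF distance is symmetric, flip-invariant and zero on identity", {
  a <- cbind(0:19, 0, 0)
  expect_equal(mdfDistance(a, a), 0)
  expect_equal(mdfDistance(a, a[20:1, ]), 0)
  b <- cbind(0:19, 3, 0)
  expect_equal(mdfDistance(a, b), 3)
  expect_equal(mdfDistance(b, a), mdfDistance(a, b))
  set.seed(3)
  for (i in 1:10) {
    x <- matrix(rnorm(60), 20, 3); y <- matrix(rnorm(60), 20, 3)
    expect_equal(mdfDistance(x, y), mdfDistance(y, x), tolerance = 1e-12)
    expect_gte(mdfDistance(x, y), 0)
    expect_equal(mdfDistance(x, y[20:1, ]), mdfDistance(x, y), tolerance = 1e-12)
  }
  expect_error(mdfDistance(a, cbind(0:9, 0, 0)), "equal point counts")
})

test_that("pairwise distance matrix matches per-pair MDF calls", {
  ident <- replicate(3, cbind(0:19, 0, 0), simplify = FALSE)
  expect_equal(mdfDistanceMatrix(ident), matrix(0, 3, 3))

  set.seed(9)
  sl <- replicate(10, matrix(cumsum(rnorm(60, sd = 2)), 20, 3),
                  simplify = FALSE)
  dm <- mdfDistanceMatrix(sl)
  expect_equal(dm, t(dm))
  expect_equal(diag(dm), rep(0, 10))
  # brute-force element-wise oracle
  for (i in 1:10) for (j in 1:10)
    expect_equal(dm[i, j], mdfDistance(sl[[i]], sl[[j]]), tolerance = 1e-6)

  expect_error(mdfDistanceMatrix(list()), "at least 2|empty")
})

test_that("U-shape test applies the chord criterion and length bounds", {
  # straight segment: D = L > L/pi
  expect_false(isUShaped(lineStreamline(c(0, 0, 0), c(50, 0, 0))))

  # 3/4 circle radius 10: L = 15*pi ~ 47.1, D = 10*sqrt(2) < L/pi = 15
  u <- arcStreamline(10, 0.75)
  expect_equal(arcLength(u), 15 * pi, tolerance = 1e-3)
  expect_equal(endpointDistance(u), 10 * sqrt(2), tolerance = 1e-4)
  expect_true(isUShaped(u))

  # semicircle: D/L = 2/pi > 1/pi, fails the chord criterion
  expect_false(isUShaped(arcStreamline(15, 0.5)))

  # length bounds on L by default
  expect_false(isUShaped(arcStreamline(3, 0.75)))    # L ~ 14.1 < 20
  expect_false(isUShaped(arcStreamline(20, 0.75)))   # L ~ 94.2 > 80
  # endpoint-bound mode bounds D instead: D = 3*sqrt(2) ~ 4.2 < 20 fails;
  # radius 20 gives D ~ 28.3 within [20, 80] and passes
  expect_false(isUShaped(arcStreamline(3, 0.75), boundOn = "endpoint"))
  expect_true(isUShaped(arcStreamline(20, 0.75), boundOn = "endpoint"))
})

test_that("midline crossing needs strictly opposite sides", {
  expect_false(crossesMidline(lineStreamline(c(3, 0, 0), c(8, 5, 0))))
  expect_true(crossesMidline(lineStreamline(c(-5, 0, 0), c(5, 0, 0))))
  # touches x = 0 without changing sign
  touch <- rbind(c(2, 0, 0), c(0, 1, 0), c(3, 2, 0))
  expect_false(crossesMidline(touch))
  # sign-scan oracle over point pairs
  set.seed(5)
  for (i in 1:20) {
    s <- matrix(rnorm(30), 10, 3)
    oracle <- any(outer(s[, 1] > 0, s[, 1] < 0, `&`))
    expect_identical(crossesMidline(s), oracle)
  }
})

test_that("U-shape filter keeps planted arcs, drops lines, and is idempotent", {
  arcs <- lapply(1:10, function(i)
    arcStreamline(10, 0.75, n = 100, center = c(30 + i, i, 0)))
  lines <- lapply(1:10, function(i)
    lineStreamline(c(10, i, 0), c(60, i, 0), 50))
  t <- tractogram(c(arcs, lines))
  fl <- filterUShaped(t)
  expect_identical(fl$indices, 1:10)
  expect_equal(nStreamlines(fl$tractogram), 10L)
  # straight lines only -> empty result is allowed
  expect_length(filterUShaped(tractogram(lines))$indices, 0)
  # idempotence
  again <- filterUShaped(fl$tractogram)
  expect_identical(again$indices, seq_along(fl$indices))

  # retained set is invariant under a rigid transform that keeps the
  # midline relationship (pure translation along y/z + rotation about x)
  rot <- lapply(c(arcs, lines), function(s)
    rigidTransform(s, angle = 0.5, axis = c(1, 0, 0), translation = c(0, 7, -4)))
  expect_identical(filterUShaped(tractogram(rot))$indices, fl$indices)
})
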