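test_that("tract and average centroids behave under offsets and flips", {
  a <- cbind(0:19, 0, 0)
  expect_equal(tractCentroid(list(a, a, a)), a, ignore_attr = TRUE)
  up <- cbind(0:19, 1, 0); dn <- cbind(0:19, -1, 0)
  expect_equal(tractCentroid(list(up, dn)), a, ignore_attr = TRUE)
  expect_equal(tractCentroid(list(a, a[20:1, ])), a, ignore_attr = TRUE,
               tolerance = 1e-9)

  # average centroid: identical, symmetric offset, and shrinkage with k
  expect_equal(averageCentroid(list(a, a, a)), a, ignore_attr = TRUE)
  hi <- a + matrix(c(0, 0, 1), 20, 3, byrow = TRUE)
  lo <- a - matrix(c(0, 0, 1), 20, 3, byrow = TRUE)
  expect_equal(averageCentroid(list(hi, lo)), a, ignore_attr = TRUE)
  expect_equal(centroidDistance(hi, averageCentroid(list(hi, lo))), 1)
  expect_equal(centroidDistance(a, a), 0)
  expect_equal(centroidDistance(a, a[20:1, ]), 0)  # flip invariance

  # Monte-Carlo: per-point deviation of the average from truth ~ sigma/sqrt(k)
  set.seed(31)
  sigma <- 1; ks <- c(4, 16)
  devs <- vapply(ks, function(k) {
    mean(replicate(200, {
      cens <- lapply(seq_len(k), function(i)
        a + matrix(rnorm(60, sd = sigma), 20, 3))
      avg <- averageCentroid(cens)
      mean(sqrt(rowSums((avg - a)^2)))
    }))
  }, 0)
  # quadrupling k halves the deviation
  expect_equal(devs[1] / devs[2], 2, tolerance = 0.15)
})

test_that("density maps count each streamline once per voxel", {
  # one straight streamline along a voxel row
  s <- lineStreamline(c(0, 0, 0), c(3, 0, 0), 50)
  m <- densityMap(list(s), c(4L, 4L, 4L), diag(4))
  arr <- densityArray(m)
  expect_equal(arr[1:4, 1, 1], rep(1, 4))
  expect_equal(sum(arr), 4)

  # {a,b} vs {b,c} hand count
  s1 <- lineStreamline(c(0, 0, 0), c(1, 0, 0), 20)   # voxels a, b
  s2 <- lineStreamline(c(1, 0, 0), c(2, 0, 0), 20)   # voxels b, c
  m2 <- densityMap(list(s1, s2), c(4L, 4L, 4L), diag(4))
  a2 <- densityArray(m2)
  expect_equal(a2[1:3, 1, 1], c(0.5, 1, 0.5))

  # duplicating streamlines leaves fractions unchanged
  m3 <- densityMap(list(s1, s1, s2, s2), c(4L, 4L, 4L), diag(4))
  expect_equal(densityArray(m3), a2)

  # points outside the grid are ignored with a warning
  out <- lineStreamline(c(0, 0, 0), c(10, 0, 0), 50)
  expect_warning(m4 <- densityMap(list(out), c(4L, 4L, 4L), diag(4)),
                 "outside")
  expect_equal(max(densityArray(m4)), 1)
})

test_that("wDSC matches hand-computed overlap values exactly", {
  A <- handDensityMap(c(`1` = 1, `2` = 1), 1)
  B <- handDensityMap(c(`2` = 1, `3` = 1), 1)
  expect_equal(wdsc(A, A), 1, tolerance = 1e-12)
  expect_equal(wdsc(A, B), 0.5, tolerance = 1e-12)  # (1+1)/(2+2)
  disj <- handDensityMap(c(`10` = 1), 1)
  expect_equal(wdsc(A, disj), 0)

  # weighted cases by independent summation
  W1 <- handDensityMap(c(`1` = 0.8, `2` = 0.6, `3` = 0.2), 5)
  W2 <- handDensityMap(c(`2` = 0.9, `3` = 0.1, `4` = 0.4), 5)
  # intersection voxels {2,3}: (0.6+0.2 + 0.9+0.1) / (1.6 + 1.4)
  expect_equal(wdsc(W1, W2), (0.6 + 0.2 + 0.9 + 0.1) / (1.6 + 1.4),
               tolerance = 1e-12)
  W3 <- handDensityMap(c(`1` = 0.25, `5` = 1), 4)
  # intersection {1}: (0.8 + 0.25) / (1.6 + 1.25)
  expect_equal(wdsc(W1, W3), 1.05 / 2.85, tolerance = 1e-12)

  # symmetry and range
  expect_equal(wdsc(W1, W2), wdsc(W2, W1), tolerance = 1e-15)
  expect_gte(wdsc(W1, W2), 0); expect_lte(wdsc(W1, W2), 1)

  # removing an intersection voxel never increases wDSC
  W2e <- handDensityMap(c(`3` = 0.1, `4` = 0.4), 5)
  expect_lte(wdsc(W1, W2e), wdsc(W1, W2))

  # both empty -> 0 with a message
  E <- handDensityMap(setNames(numeric(0), character(0)), 1)
  expect_message(z <- wdsc(E, E), "empty")
  expect_equal(z, 0)
  expect_error(wdsc(A, handDensityMap(c(`1` = 1), 1, refDim = c(9L, 9L, 9L))),
               "different grids")
})

test_that("mean pairwise wDSC enumerates all subject pairs", {
  A <- handDensityMap(c(`1` = 1, `2` = 1), 1)
  B <- handDensityMap(c(`2` = 1, `3` = 1), 1)
  expect_equal(pairwiseWdscMean(list(A, A, A)), 1)
  # pairs: (A,A)=1, (A,B)=0.5, (A,B)=0.5 -> 2/3
  expect_equal(pairwiseWdscMean(list(A, A, B)), 2 / 3, tolerance = 1e-12)
  expect_equal(pairwiseWdscMean(list(B, A, A)), 2 / 3, tolerance = 1e-12)
  expect_error(pairwiseWdscMean(list(A)), "2 subjects")
})

test_that("scalar sampling is trilinear and reproduces linear fields", {
  dm <- c(10L, 10L, 10L)
  const <- array(3.5, dm)
  s <- lineStreamline(c(1, 1, 1), c(8, 8, 8), 20)
  expect_equal(mapScalarAlong(s, const, diag(4)), rep(3.5, 20))

  # linear field f(world) = x is reproduced exactly by trilinear interpolation
  xs <- array(rep(0:9, 100), dm)
  sx <- lineStreamline(c(0.3, 2, 2), c(8.7, 2, 2), 20)
  expect_equal(mapScalarAlong(sx, xs, diag(4)), sx[, 1], tolerance = 1e-6)

  # exact voxel center returns that voxel's value
  set.seed(12)
  vol <- array(runif(1000), dm)
  p <- rbind(c(3, 4, 5), c(0, 0, 0))
  expect_equal(mapScalarAlong(p, vol, diag(4)),
               c(vol[4, 5, 6], vol[1, 1, 1]))

  # out-of-grid points become NA
  far <- rbind(c(-5, 0, 0), c(2, 2, 2))
  v <- mapScalarAlong(far, vol, diag(4))
  expect_true(is.na(v[1]) && !is.na(v[2]))
})

test_that("tract profiles average aligned members", {
  dm <- c(10L, 10L, 10L)
  xs <- array(rep(0:9, 100), dm)
  s <- lineStreamline(c(1, 2, 2), c(8, 2, 2), 20)
  single <- tractProfile(list(s), xs, diag(4))
  expect_equal(single, s[, 1], tolerance = 1e-6)
  # a reversed copy contributes identically after alignment
  both <- tractProfile(list(s, s[20:1, ]), xs, diag(4))
  expect_equal(both, single, tolerance = 1e-9)
  # constant field -> constant profile
  expect_equal(tractProfile(list(s), array(2, dm), diag(4)), rep(2, 20))
})

test_that("ICC(A,1) matches an independent ANOVA oracle", {
  # oracle: two-way ANOVA mean squares via aov(), ICC from McGraw-Wong
  iccOracle <- function(m) {
    df <- data.frame(y = as.vector(m),
                     subj = factor(rep(seq_len(nrow(m)), ncol(m))),
                     samp = factor(rep(seq_len(ncol(m)), each = nrow(m))))
    ms <- summary(aov(y ~ subj + samp, data = df))[[1]][["Mean Sq"]]
    n <- nrow(m); k <- ncol(m)
    (ms[1] - ms[3]) / (ms[1] + (k - 1) * ms[3] + (k / n) * (ms[2] - ms[3]))
  }
  set.seed(77)
  m <- matrix(rnorm(24), 4, 6)
  res <- iccAbsolute(m)
  expect_equal(res$icc, iccOracle(m), tolerance = 1e-10)
  expect_false(res$degenerate)
  expect_true(res$lower <= res$icc && res$icc <= res$upper)

  # structured case: strong subject effect
  m2 <- outer(c(0, 2, 4, 6, 8), rep(1, 6)) + matrix(rnorm(30, sd = 0.1), 5, 6)
  res2 <- iccAbsolute(m2)
  expect_equal(res2$icc, iccOracle(m2), tolerance = 1e-10)
  expect_gt(res2$icc, 0.9)

  # global shift invariance
  expect_equal(iccAbsolute(m + 100)$icc, res$icc, tolerance = 1e-8)

  # identical profiles with along-tract variance: perfect agreement
  flat <- matrix(rep(sin(1:10), 3), 3, 10, byrow = TRUE)
  dres <- iccAbsolute(flat)
  expect_true(dres$degenerate)
  expect_equal(dres$icc, 1)

  # missing columns dropped listwise with a message
  m3 <- m; m3[2, 4] <- NA
  expect_message(r3 <- iccAbsolute(m3), "dropped 1")
  expect_equal(r3$icc, iccOracle(m[, -4]), tolerance = 1e-10)

  # average-measure form is bounded by the single-measure form
  expect_gte(iccAbsolute(m2, type = "average")$icc, res2$icc)
})

test_that("streamline-count CV uses the sample SD in percent", {
  expect_equal(streamlineCV(c(10, 10, 10)), 0)
  expect_equal(streamlineCV(c(5, 10, 15)), 50)   # sd 5 / mean 10
  expect_equal(streamlineCV(7 * c(5, 10, 15)), 50)  # scale invariance
  z <- streamlineCV(c(0, 0, 0))
  expect_true(is.na(z))
  expect_true(attr(z, "zeroCount"))
})

test_that("metric correlations use Spearman ranks and BH adjustment", {
  tab <- data.frame(a = 1:8, b = (1:8)^2, c = -(1:8) + 0.5 * c(1:4, 1:4))
  res <- metricCorrelations(tab, metrics = c("a", "b"), logCounts = FALSE)
  expect_equal(res$rho, 1)
  res2 <- metricCorrelations(data.frame(a = 1:8, d = exp(-(1:8))),
                             metrics = c("a", "d"), logCounts = FALSE)
  expect_equal(res2$rho, -1)

  # ties: matches the rank-then-Pearson oracle
  set.seed(5)
  x <- c(1, 2, 2, 3, 4, 4, 4, 7); y <- rnorm(8)
  tab3 <- data.frame(x = x, y = y, z = rnorm(8))
  res3 <- metricCorrelations(tab3, metrics = c("x", "y", "z"),
                             logCounts = FALSE)
  r_xy <- res3$rho[res3$metric_i == "x" & res3$metric_j == "y"]
  expect_equal(r_xy, cor(rank(x), rank(y)), tolerance = 1e-12)

  # BH step-up on a known p-vector
  expect_equal(p.adjust(c(0.01, 0.02, 0.04, 0.5), method = "BH"),
               c(0.04, 0.04, 16 / 300, 0.5), tolerance = 1e-12)
  # and the q column is the BH adjustment of the p column
  expect_equal(res3$q, p.adjust(res3$p, method = "BH"), tolerance = 1e-12)

  # constant column -> rho missing
  tabc <- data.frame(u = rep(1, 8), v = 1:8, w = rnorm(8))
  resc <- metricCorrelations(tabc, metrics = c("u", "v", "w"),
                             logCounts = FALSE)
  expect_true(is.na(resc$rho[resc$metric_i == "u" & resc$metric_j == "v"]))

  expect_error(metricCorrelations(data.frame(a = 1:3, b = 1:3),
                                  metrics = c("a", "b"), logCounts = FALSE),
               "at least 4")
})

test_that("endpoints are assigned to the nearest parcel within the radius", {
  lab <- array(0L, c(10L, 10L, 10L))
  lab[2, 2, 2] <- 3L    # parcel 3 at voxel center (1,1,1)
  lab[8, 2, 2] <- 7L    # parcel 7 at voxel center (7,1,1)
  # endpoint inside a labeled voxel -> that label
  s1 <- lineStreamline(c(1, 1, 1), c(7, 1, 1), 20)
  res <- assignEndpointsToParcels(list(s1), lab, diag(4), radius = 4)
  expect_identical(res$parcelA, 3L)
  expect_identical(res$parcelB, 7L)

  # endpoint 3 mm from parcel 3, 3+ mm closer than parcel 7
  s2 <- lineStreamline(c(1, 4, 1), c(7, 4, 1), 20)
  res2 <- assignEndpointsToParcels(list(s2), lab, diag(4), radius = 4)
  expect_identical(res2$parcelA, 3L)
  # brute-force nearest-voxel oracle for the first endpoint
  nz <- which(lab != 0, arr.ind = TRUE)
  d <- sqrt(colSums((t(nz - 1) - c(1, 4, 1))^2))
  expect_identical(res2$parcelA, lab[nz[which.min(d), , drop = FALSE]])

  # beyond the radius -> unassigned
  s3 <- lineStreamline(c(1, 9, 9), c(7, 9, 9), 20)
  res3 <- assignEndpointsToParcels(list(s3), lab, diag(4), radius = 4)
  expect_true(is.na(res3$parcelA) && is.na(res3$parcelB))

  # majority vote with a reversed member still consistent
  res4 <- assignEndpointsToParcels(list(s1, s1[20:1, ]), lab, diag(4))
  expect_identical(res4$parcelA, 3L)
  expect_identical(res4$parcelB, 7L)
})
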