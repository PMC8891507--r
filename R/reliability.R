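## Reliability metric suite: tract centroids and their distances to the
## cohort-average centroid, sparse tract density maps and weighted Dice
## overlap, along-tract scalar profiles with two-way random-effects ICC,
## streamline-count coefficients of variation, inter-metric Spearman
## correlations with BH correction, and endpoint-to-parcel assignment.

#' Centroid of a tract
#'
#' Orientation-aligns the members to the first streamline (flipping a member
#' iff its flipped orientation is closer), then averages each sample point's
#' coordinates across members.
#'
#' @param sl list of resampled `n x 3` streamlines (common n) or a
#'   [Tractogram-class].
#' @return `n x 3` centroid matrix with attribute `size`.
#' @export
tractCentroid <- function(sl) {
  if (is(sl, "Tractogram")) sl <- streamlines(sl)
  if (!length(sl)) stop("empty tract", call. = FALSE)
  ref <- sl[[1]]
  aligned <- alignToReference(sl, ref)
  cen <- Reduce(`+`, aligned) / length(aligned)
  attr(cen, "size") <- length(sl)
  cen
}

#' Average centroid across subjects or sessions
#'
#' Aligns each subject centroid to the first (flip rule as in
#' [tractCentroid()]) and averages per sample point. This is the cohort
#' reference curve the per-subject centroid distances are measured against.
#'
#' @param centroids list of `n x 3` centroid matrices (common n).
#' @return `n x 3` average centroid.
#' @export
averageCentroid <- function(centroids) {
  stopifnot(length(centroids) >= 1L)
  aligned <- alignToReference(centroids, centroids[[1]])
  Reduce(`+`, aligned) / length(aligned)
}

#' MDF distance between a centroid and the average centroid
#'
#' @param cen,avg `n x 3` centroid matrices (common n).
#' @return distance in mm.
#' @export
centroidDistance <- function(cen, avg) mdfDistance(cen, avg)

#' Tract density map
#'
#' Each streamline is upsampled so consecutive points are less than half the
#' smallest voxel edge apart, the set of voxels containing at least one
#' upsampled point counts that streamline once, and the per-voxel fraction
#' is the count divided by the total number of streamlines. Points outside
#' the grid are ignored (warning); a streamline fully outside contributes
#' nothing.
#'
#' @param sl list of streamlines (world mm) or a [Tractogram-class].
#' @param refDim grid dimensions (taken from the tractogram if omitted).
#' @param refAffine 4x4 voxel-to-world affine.
#' @param step upsampling step in mm; default 0.45 x the smallest voxel edge.
#' @return A [TractDensityMap-class].
#' @export
densityMap <- function(sl, refDim = NULL, refAffine = NULL, step = NULL) {
  if (is(sl, "Tractogram")) {
    if (is.null(refDim)) refDim <- refDim(sl)
    if (is.null(refAffine)) refAffine <- refAffine(sl)
    sl <- streamlines(sl)
  }
  stopifnot(length(sl) >= 1L, !is.null(refDim), !is.null(refAffine))
  inv <- solve(refAffine)
  edges <- sqrt(colSums(refAffine[1:3, 1:3]^2))
  if (is.null(step)) step <- 0.45 * min(edges)
  nvox <- prod(refDim)
  counts <- integer(nvox)
  dropped <- 0L
  for (s in sl) {
    L <- arcLength(s)
    np <- max(nrow(s), ceiling(L / step) + 1L)
    p <- resampleStreamline(s, np)
    v <- cbind(p, 1) %*% t(inv)            # continuous 0-based voxel coords
    ijk <- round(v[, 1:3, drop = FALSE])
    ok <- ijk[, 1] >= 0 & ijk[, 1] < refDim[1] &
          ijk[, 2] >= 0 & ijk[, 2] < refDim[2] &
          ijk[, 3] >= 0 & ijk[, 3] < refDim[3]
    if (!all(ok)) dropped <- dropped + sum(!ok)
    ijk <- ijk[ok, , drop = FALSE]
    if (!nrow(ijk)) next
    lin <- unique(1L + ijk[, 1] + refDim[1] * (ijk[, 2] + refDim[2] * ijk[, 3]))
    counts[lin] <- counts[lin] + 1L
  }
  if (dropped > 0L)
    warning(sprintf("%d upsampled points fell outside the grid and were ignored",
                    dropped), call. = FALSE)
  idx <- which(counts > 0L)
  new("TractDensityMap", indices = idx,
      fractions = counts[idx] / length(sl),
      refDim = as.integer(refDim), refAffine = as.matrix(refAffine),
      nStreamlines = length(sl))
}

sameGrid <- function(a, b) {
  all(a@refDim == b@refDim) && max(abs(a@refAffine - b@refAffine)) < 1e-6
}

#' Weighted Dice similarity coefficient of two density maps
#'
#' `wDSC(A, B) = (sum_{v'} A_{v'} + sum_{v'} B_{v'}) / (sum_v A_v + sum_v B_v)`
#' where `v'` ranges over voxels where both maps are positive. Weighs the
#' dense tract core more heavily than the stray periphery. Two empty maps
#' give 0 (with a message).
#'
#' @param A,B [TractDensityMap-class] objects on the same grid.
#' @return value in `[0, 1]`.
#' @export
wdsc <- function(A, B) {
  stopifnot(is(A, "TractDensityMap"), is(B, "TractDensityMap"))
  if (!sameGrid(A, B)) stop("density maps are on different grids", call. = FALSE)
  denom <- sum(A@fractions) + sum(B@fractions)
  if (denom == 0) {
    message("wdsc: both density maps are empty; returning 0")
    return(0)
  }
  common <- intersect(A@indices, B@indices)
  if (!length(common)) return(0)
  num <- sum(A@fractions[match(common, A@indices)]) +
         sum(B@fractions[match(common, B@indices)])
  num / denom
}

#' Mean pairwise wDSC across subjects
#'
#' @param maps list of per-subject [TractDensityMap-class]s for one tract.
#' @return mean of [wdsc()] over all unordered subject pairs.
#' @export
pairwiseWdscMean <- function(maps) {
  if (length(maps) < 2L) stop("need at least 2 subjects", call. = FALSE)
  pr <- combn(length(maps), 2L)
  mean(apply(pr, 2L, function(p) wdsc(maps[[p[1]]], maps[[p[2]]])))
}

#' Sample a scalar volume along a streamline
#'
#' Trilinear interpolation of the volume at each world-space point
#' (world -> continuous voxel via the inverse affine). Points outside the
#' grid return `NA`.
#'
#' @param s `n x 3` streamline matrix (world mm).
#' @param volume 3D numeric array.
#' @param refAffine 4x4 voxel-to-world affine of the volume.
#' @return numeric vector of length `nrow(s)`.
#' @export
mapScalarAlong <- function(s, volume, refAffine) {
  checkStreamline(s)
  dm <- dim(volume)
  v <- cbind(s, 1) %*% t(solve(refAffine))
  x <- v[, 1]; y <- v[, 2]; z <- v[, 3]
  x0 <- floor(x); y0 <- floor(y); z0 <- floor(z)
  fx <- x - x0; fy <- y - y0; fz <- z - z0
  # clamp the upper corner so points exactly on the last slice interpolate
  ok <- x >= 0 & x <= dm[1] - 1 & y >= 0 & y <= dm[2] - 1 & z >= 0 & z <= dm[3] - 1
  x1 <- pmin(x0 + 1, dm[1] - 1); y1 <- pmin(y0 + 1, dm[2] - 1); z1 <- pmin(z0 + 1, dm[3] - 1)
  g <- function(i, j, k) volume[cbind(pmax(i, 0) + 1, pmax(j, 0) + 1, pmax(k, 0) + 1)]
  val <- g(x0, y0, z0) * (1 - fx) * (1 - fy) * (1 - fz) +
         g(x1, y0, z0) * fx * (1 - fy) * (1 - fz) +
         g(x0, y1, z0) * (1 - fx) * fy * (1 - fz) +
         g(x0, y0, z1) * (1 - fx) * (1 - fy) * fz +
         g(x1, y1, z0) * fx * fy * (1 - fz) +
         g(x1, y0, z1) * fx * (1 - fy) * fz +
         g(x0, y1, z1) * (1 - fx) * fy * fz +
         g(x1, y1, z1) * fx * fy * fz
  val[!ok] <- NA_real_
  val
}

#' Along-tract scalar profile
#'
#' Orientation-aligns the tract members (flip rule as in [tractCentroid()]),
#' samples the volume along each with [mapScalarAlong()], and averages per
#' sample index ignoring missing values.
#'
#' @param sl list of resampled streamlines (common n) or [Tractogram-class].
#' @param volume 3D scalar array (e.g. an FA map).
#' @param refAffine 4x4 voxel-to-world affine of the volume.
#' @return numeric vector of n per-sample means.
#' @export
tractProfile <- function(sl, volume, refAffine) {
  if (is(sl, "Tractogram")) { refAffine <- refAffine(sl); sl <- streamlines(sl) }
  if (!length(sl)) stop("empty tract", call. = FALSE)
  aligned <- alignToReference(sl, sl[[1]])
  vals <- vapply(aligned, mapScalarAlong, numeric(nrow(sl[[1]])),
                 volume = volume, refAffine = refAffine)
  rowMeans(as.matrix(vals), na.rm = TRUE)
}

#' Two-way random-effects absolute-agreement ICC
#'
#' Computes ICC(A,1) (single measurement) or ICC(A,k) (average measurement)
#' from the two-way ANOVA decomposition of a subjects x samples matrix,
#' following the two-way random-effects, absolute-agreement model. With
#' rows = subjects (targets) and columns = along-tract samples (raters):
#' `ICC(A,1) = (MSR - MSE) / (MSR + (k-1) MSE + (k/n) (MSC - MSE))`.
#' The 95% confidence interval uses the standard F-based approximation.
#' Columns containing missing values are dropped listwise (message).
#'
#' @param profiles numeric matrix, subjects in rows, samples in columns.
#' @param type `"single"` for ICC(A,1) (default) or `"average"` for ICC(A,k).
#' @param conf confidence level (default 0.95).
#' @return list with `icc`, `lower`, `upper`, `type`, `degenerate` (TRUE when
#'   the total variance is zero, in which case `icc = 1`), and the mean
#'   squares `msr`, `msc`, `mse`.
#' @export
iccAbsolute <- function(profiles, type = c("single", "average"), conf = 0.95) {
  type <- match.arg(type)
  profiles <- as.matrix(profiles)
  bad <- apply(profiles, 2L, function(v) any(!is.finite(v)))
  if (any(bad)) {
    message(sprintf("iccAbsolute: dropped %d column(s) with missing values",
                    sum(bad)))
    profiles <- profiles[, !bad, drop = FALSE]
  }
  n <- nrow(profiles); k <- ncol(profiles)
  if (n < 2L || k < 2L)
    stop("need at least 2 subjects and 2 samples", call. = FALSE)
  gm <- mean(profiles)
  rm_ <- rowMeans(profiles); cm <- colMeans(profiles)
  ssr <- k * sum((rm_ - gm)^2)
  ssc <- n * sum((cm - gm)^2)
  sst <- sum((profiles - gm)^2)
  sse <- sst - ssr - ssc
  msr <- ssr / (n - 1); msc <- ssc / (k - 1)
  mse <- sse / ((n - 1) * (k - 1))
  # degenerate perfect agreement: no between-subject variance and no
  # residual (identical rows, possibly with along-tract variance), or no
  # variance at all -> ICC = 1 by convention, flagged
  tol <- .Machine$double.eps * max(1, abs(gm))^2 * n * k * 100
  if (sst < tol || (ssr < tol && abs(sse) < tol))
    return(list(icc = 1, lower = NA_real_, upper = NA_real_, type = type,
                degenerate = TRUE, msr = msr, msc = msc, mse = mse))
  alpha <- 1 - conf
  if (type == "single") {
    icc <- (msr - mse) / (msr + (k - 1) * mse + (k / n) * (msc - mse))
    a <- (k * icc) / (n * (1 - icc))
    b <- 1 + (k * icc * (n - 1)) / (n * (1 - icc))
    v <- (a * msc + b * mse)^2 /
      ((a * msc)^2 / (k - 1) + (b * mse)^2 / ((n - 1) * (k - 1)))
    fl <- qf(1 - alpha / 2, n - 1, v)
    fu <- qf(1 - alpha / 2, v, n - 1)
    lower <- n * (msr - fl * mse) /
      (fl * (k * msc + (k * n - k - n) * mse) + n * msr)
    upper <- n * (fu * msr - mse) /
      (k * msc + (k * n - k - n) * mse + n * fu * msr)
  } else {
    icc <- (msr - mse) / (msr + (msc - mse) / n)
    i1 <- (msr - mse) / (msr + (k - 1) * mse + (k / n) * (msc - mse))
    a <- (k * i1) / (n * (1 - i1))
    b <- 1 + (k * i1 * (n - 1)) / (n * (1 - i1))
    v <- (a * msc + b * mse)^2 /
      ((a * msc)^2 / (k - 1) + (b * mse)^2 / ((n - 1) * (k - 1)))
    fl <- qf(1 - alpha / 2, n - 1, v)
    fu <- qf(1 - alpha / 2, v, n - 1)
    l1 <- n * (msr - fl * mse) /
      (fl * (k * msc + (k * n - k - n) * mse) + n * msr)
    u1 <- n * (fu * msr - mse) /
      (k * msc + (k * n - k - n) * mse + n * fu * msr)
    lower <- l1 * k / (1 + l1 * (k - 1))
    upper <- u1 * k / (1 + u1 * (k - 1))
  }
  list(icc = icc, lower = lower, upper = upper, type = type,
       degenerate = FALSE, msr = msr, msc = msc, mse = mse)
}

#' Coefficient of variation of per-subject streamline counts
#'
#' `CV = sample SD / mean x 100` (percent). A zero mean (the tract has no
#' streamlines anywhere) is undefined and returns `NA` with attribute
#' `zeroCount = TRUE`.
#'
#' @param counts numeric vector of per-subject streamline counts (>= 2).
#' @return CV in percent.
#' @examples
#' streamlineCV(c(5, 10, 15))  # 50
#' @export
streamlineCV <- function(counts) {
  stopifnot(length(counts) >= 2L)
  m <- mean(counts)
  if (m == 0) return(structure(NA_real_, zeroCount = TRUE))
  100 * stats::sd(counts) / m
}

#' Spearman correlations between reliability metrics
#'
#' Spearman rank correlation (average ranks for ties) for every unordered
#' pair of metric columns across tracts, with two-sided p-values and
#' Benjamini-Hochberg adjusted q-values across all pairs tested. Streamline
#' counts should be entered log-transformed (done automatically when a
#' `mean_count` column is present and `logCounts = TRUE`). Rows with missing
#' values in a pair are dropped listwise; constant columns give `NA` rho.
#'
#' @param table data.frame with one row per tract and numeric metric columns.
#' @param metrics character vector of column names to correlate; default all
#'   numeric columns except identifiers.
#' @param logCounts replace `mean_count` by `log(mean_count)` first.
#' @return data.frame with columns `metric_i`, `metric_j`, `rho`, `p`, `q`,
#'   `n`.
#' @export
metricCorrelations <- function(table, metrics = NULL, logCounts = TRUE) {
  tab <- as.data.frame(table)
  if (logCounts && "mean_count" %in% names(tab)) {
    tab$log_count <- log(tab$mean_count)
    tab$mean_count <- NULL
  }
  if (is.null(metrics)) {
    num <- vapply(tab, is.numeric, logical(1))
    metrics <- setdiff(names(tab)[num], c("tract", "tract_id", "n_subjects",
                                          "icc_lower", "icc_upper"))
  }
  if (nrow(tab) < 4L) stop("need at least 4 tracts", call. = FALSE)
  pr <- combn(metrics, 2L)
  res <- data.frame(metric_i = pr[1, ], metric_j = pr[2, ],
                    rho = NA_real_, p = NA_real_, q = NA_real_,
                    n = NA_integer_, stringsAsFactors = FALSE)
  for (i in seq_len(ncol(pr))) {
    x <- tab[[pr[1, i]]]; y <- tab[[pr[2, i]]]
    ok <- is.finite(x) & is.finite(y)
    res$n[i] <- sum(ok)
    if (sum(ok) < 4L) next
    x <- x[ok]; y <- y[ok]
    if (stats::sd(x) == 0 || stats::sd(y) == 0) next  # rho undefined
    ct <- suppressWarnings(stats::cor.test(x, y, method = "spearman",
                                           exact = FALSE))
    res$rho[i] <- unname(ct$estimate)
    res$p[i] <- ct$p.value
  }
  tested <- !is.na(res$p)
  res$q[tested] <- p.adjust(res$p[tested], method = "BH")
  res
}

#' Assign tract endpoints to parcellation labels
#'
#' For each streamline endpoint the candidate parcel is the nearest
#' non-background label voxel center within `radius` mm (world space). Per
#' tract end, the parcel receiving the most endpoints wins (ties to the
#' lowest label id); an end with no candidates is unassigned (`NA`).
#' Streamlines are orientation-aligned to the first member so "end A" and
#' "end B" are consistent across the tract.
#'
#' @param sl list of resampled streamlines (common n) or [Tractogram-class].
#' @param labelVolume 3D integer array, 0 = background.
#' @param refAffine 4x4 voxel-to-world affine of the label volume.
#' @param radius search radius in mm (default 4).
#' @return list with `parcelA`, `parcelB` (label ids or `NA`), and
#'   `endpointLabels`, a 2-column matrix of per-streamline end assignments.
#' @export
assignEndpointsToParcels <- function(sl, labelVolume, refAffine, radius = 4) {
  if (is(sl, "Tractogram")) { refAffine <- refAffine(sl); sl <- streamlines(sl) }
  stopifnot(length(sl) >= 1L, radius > 0)
  aligned <- alignToReference(sl, sl[[1]])
  nz <- which(labelVolume != 0, arr.ind = TRUE)
  if (!nrow(nz)) {
    na2 <- matrix(NA_integer_, length(sl), 2)
    return(list(parcelA = NA_integer_, parcelB = NA_integer_,
                endpointLabels = na2))
  }
  centers <- cbind(nz - 1, 1) %*% t(refAffine)  # world coords of voxel centers
  centers <- centers[, 1:3, drop = FALSE]
  labs <- labelVolume[nz]
  nearestParcel <- function(p) {
    d2 <- colSums((t(centers) - p)^2)
    j <- which.min(d2)
    if (sqrt(d2[j]) <= radius) labs[j] else NA_integer_
  }
  ends <- t(vapply(aligned, function(s)
    c(nearestParcel(s[1, ]), nearestParcel(s[nrow(s), ])), integer(2)))
  vote <- function(v) {
    v <- v[!is.na(v)]
    if (!length(v)) return(NA_integer_)
    tb <- table(v)
    winners <- as.integer(names(tb)[tb == max(tb)])
    min(winners)                         # ties -> lowest label id
  }
  list(parcelA = vote(ends[, 1]), parcelB = vote(ends[, 2]),
       endpointLabels = ends)
}
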