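## Template bundle clustering: outlier pruning on the MDF distance matrix,
## Gaussian affinity, normalized spectral clustering, QuickBundles, and
## orientation-aligned cluster centroids.

#' Prune distance-matrix outliers
#'
#' For each streamline, computes the mean MDF distance to all other
#' streamlines (row mean excluding the diagonal) and discards streamlines
#' whose mean exceeds the grand mean by more than two sample standard
#' deviations.
#'
#' @param dm symmetric MDF distance matrix.
#' @param nSd outlier threshold in standard deviations (default 2).
#' @return Integer vector of retained indices (original order preserved).
#' @export
removeOutliers <- function(dm, nSd = 2) {
  stopifnot(is.matrix(dm), nrow(dm) == ncol(dm), nrow(dm) >= 3L)
  n <- nrow(dm)
  m <- (rowSums(dm) - diag(dm)) / (n - 1)
  thr <- mean(m) + nSd * stats::sd(m)
  keep <- which(m <= thr | is.na(thr))
  if (!length(keep))
    stop("outlier removal discarded every streamline (degenerate configuration)",
         call. = FALSE)
  keep
}

#' Gaussian affinity from an MDF distance matrix
#'
#' `w_ij = exp(-d_ij^2 / (2 sigma^2))`. The kernel width reading of
#' "a Gaussian kernel with a width of sigma mm" is sigma in this
#' expression; the diagonal is exactly 1.
#'
#' @param dm symmetric distance matrix (mm).
#' @param sigma kernel width in mm (default 8, the whole-brain setting; 6 mm
#'   is used for U-shaped tract clustering).
#' @return Symmetric affinity matrix with unit diagonal, entries in (0, 1].
#' @export
gaussianAffinity <- function(dm, sigma = 8) {
  if (sigma <= 0) stop("sigma must be > 0", call. = FALSE)
  w <- exp(-dm^2 / (2 * sigma^2))
  diag(w) <- 1
  w
}

## canonical labels: clusters ordered by descending size, ties by lowest
## member index; returns labels in 0 .. k-1
canonicalizeLabels <- function(raw) {
  ids <- sort(unique(raw))
  size <- vapply(ids, function(i) sum(raw == i), 0L)
  first <- vapply(ids, function(i) which(raw == i)[1], 0L)
  ord <- ids[order(-size, first)]
  match(raw, ord) - 1L
}

#' Normalized spectral clustering of an affinity matrix
#'
#' Ng-Jordan-Weiss style: form the symmetric normalized Laplacian
#' `L_sym = I - D^{-1/2} W D^{-1/2}`, take the eigenvectors of its k
#' smallest eigenvalues, row-normalize the n x k embedding, and run k-means
#' with a fixed seed and multiple restarts. Cluster ids are canonical
#' (descending size, ties by lowest member index), so the output is
#' deterministic given `(aff, k, seed)`.
#'
#' @param aff symmetric affinity matrix (see [gaussianAffinity()]).
#' @param k number of clusters (800 for whole-brain templates, 500 for
#'   U-shaped tract templates in the reference workflow).
#' @param seed integer seed for the embedded k-means.
#' @param nstart k-means restarts (default 10).
#' @return A [ClusterLabeling-class] with labels `0 ... k-1`.
#' @export
spectralCluster <- function(aff, k, seed = 1L, nstart = 10L) {
  stopifnot(is.matrix(aff), nrow(aff) == ncol(aff))
  n <- nrow(aff)
  if (k > n) stop(sprintf("k = %d exceeds the number of streamlines (%d)", k, n),
                  call. = FALSE)
  if (max(abs(aff - t(aff))) > 1e-8)
    stop("affinity matrix must be symmetric", call. = FALSE)
  deg <- rowSums(aff)
  if (any(deg <= 0))
    stop(sprintf("zero-degree row(s) in affinity matrix: %s",
                 paste(which(deg <= 0), collapse = ", ")), call. = FALSE)
  if (k == 1L)
    return(clusterLabeling(rep(0L, n), 1L, "spectral",
                           list(k = 1L, seed = seed)))
  dis <- 1 / sqrt(deg)
  lsym <- diag(n) - (dis * aff) * rep(dis, each = n)  # D^-1/2 W D^-1/2 scaled
  lsym <- (lsym + t(lsym)) / 2
  ev <- eigen(lsym, symmetric = TRUE)
  # eigen() returns eigenvalues in decreasing order; the k smallest are last
  emb <- ev$vectors[, n:(n - k + 1L), drop = FALSE]
  rn <- sqrt(rowSums(emb^2))
  rn[rn == 0] <- 1
  emb <- emb / rn
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  set.seed(seed)
  km <- kmeansRestarts(emb, k, nstart)
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  clusterLabeling(canonicalizeLabels(km$cluster), k, "spectral",
                  list(k = k, seed = seed, nstart = nstart))
}

## k-means++ seeding (probability proportional to squared distance from the
## chosen centers) with restarts; plain random starts routinely land in
## split/merge local optima on well-separated spectral embeddings.
kmeansRestarts <- function(emb, k, nstart) {
  if (k >= nrow(emb))             # every point its own cluster
    return(list(cluster = seq_len(nrow(emb)), tot.withinss = 0))
  best <- NULL
  for (r in seq_len(nstart)) {
    centers <- matrix(0, k, ncol(emb))
    centers[1, ] <- emb[sample.int(nrow(emb), 1L), ]
    d2 <- colSums((t(emb) - centers[1, ])^2)
    for (j in seq_len(k - 1L) + 1L) {
      prob <- d2 / sum(d2)
      pick <- if (all(d2 == 0)) sample.int(nrow(emb), 1L)
              else sample.int(nrow(emb), 1L, prob = prob)
      centers[j, ] <- emb[pick, ]
      d2 <- pmin(d2, colSums((t(emb) - centers[j, ])^2))
    }
    km <- suppressWarnings(stats::kmeans(emb, centers = centers,
                                         iter.max = 200L))
    if (is.null(best) || km$tot.withinss < best$tot.withinss) best <- km
  }
  best
}

## distances from one flat streamline (npts x 3) to a set of centroids held
## as an (npts x 3 x k) array; returns direct and flipped mean distances
.centroidDists <- function(pts, carr) {
  k <- dim(carr)[3]
  npts <- dim(carr)[1]
  dif <- carr - as.vector(pts)              # recycles pts over the 3rd dim
  pn <- sqrt(dif[, 1, , drop = FALSE]^2 + dif[, 2, , drop = FALSE]^2 +
             dif[, 3, , drop = FALSE]^2)
  direct <- colMeans(matrix(pn, npts, k))
  dif <- carr - as.vector(pts[npts:1, , drop = FALSE])
  pn <- sqrt(dif[, 1, , drop = FALSE]^2 + dif[, 2, , drop = FALSE]^2 +
             dif[, 3, , drop = FALSE]^2)
  flip <- colMeans(matrix(pn, npts, k))
  list(direct = direct, flip = flip)
}

#' QuickBundles clustering
#'
#' Single-pass clustering in input order. Each streamline is compared (MDF)
#' to every existing cluster centroid; if the minimum distance is below
#' `threshold` it joins that cluster (ties to the lowest cluster id) and the
#' centroid is updated as the exact mean of the orientation-aligned member
#' points (the incoming streamline is flipped first when its flipped
#' orientation gave the smaller distance). Otherwise the streamline seeds a
#' new cluster - unless `maxClusters` is reached, in which case it is
#' assigned to the nearest centroid regardless of threshold. Deterministic
#' given the input order.
#'
#' @param sl list of resampled `n x 3` streamlines (common n) or a
#'   [Tractogram-class].
#' @param threshold merge distance in mm (8 for whole-brain, 6 for U-tracts
#'   in the reference workflow).
#' @param maxClusters optional cap on the number of clusters (e.g. 800).
#' @return list with `labeling` (a [ClusterLabeling-class], ids by first
#'   appearance) and `centroids` (list of `n x 3` centroid matrices).
#' @export
quickBundles <- function(sl, threshold = 8, maxClusters = NULL) {
  if (is(sl, "Tractogram")) sl <- streamlines(sl)
  if (!length(sl)) stop("empty streamline collection", call. = FALSE)
  if (threshold <= 0) stop("threshold must be > 0", call. = FALSE)
  npts <- nrow(sl[[1]])
  nmax <- if (is.null(maxClusters)) length(sl) else as.integer(maxClusters)
  sums <- array(0, dim = c(npts, 3L, nmax))   # running point sums per cluster
  counts <- integer(nmax)
  k <- 0L
  labels <- integer(length(sl))
  for (i in seq_along(sl)) {
    s <- sl[[i]]
    if (nrow(s) != npts) stop("streamlines must share a common point count",
                              call. = FALSE)
    assigned <- FALSE
    if (k > 0L) {
      cen <- sums[, , seq_len(k), drop = FALSE] /
        rep(counts[seq_len(k)], each = npts * 3L)
      d <- .centroidDists(s, cen)
      dmin <- pmin(d$direct, d$flip)
      j <- which.min(dmin)                 # ties -> lowest cluster id
      if (dmin[j] < threshold || k >= nmax) {
        aligned <- if (d$flip[j] < d$direct[j]) s[npts:1, , drop = FALSE] else s
        sums[, , j] <- sums[, , j] + aligned
        counts[j] <- counts[j] + 1L
        labels[i] <- j
        assigned <- TRUE
      }
    }
    if (!assigned) {
      k <- k + 1L
      sums[, , k] <- s
      counts[k] <- 1L
      labels[i] <- k
    }
  }
  centroids <- lapply(seq_len(k), function(j) sums[, , j] / counts[j])
  list(labeling = clusterLabeling(labels - 1L, k, "quickbundles",
                                  list(threshold = threshold,
                                       maxClusters = maxClusters)),
       centroids = centroids)
}

## orientation-align a list of common-n streamlines to a reference curve:
## flip a member iff its flipped MDF to the reference is strictly smaller
alignToReference <- function(sl, ref) {
  npts <- nrow(ref)
  lapply(sl, function(s) {
    dd <- mean(sqrt(rowSums((s - ref)^2)))
    df <- mean(sqrt(rowSums((s[npts:1, , drop = FALSE] - ref)^2)))
    if (df < dd) s[npts:1, , drop = FALSE] else s
  })
}

#' Centroid of one cluster
#'
#' Members are orientation-aligned to the first member (a member is flipped
#' iff its flipped orientation is closer to the reference), then averaged
#' per sample point.
#'
#' @param sl list of resampled streamlines or a [Tractogram-class] (the full
#'   collection the labeling refers to).
#' @param labeling a [ClusterLabeling-class].
#' @param clusterId cluster id (0-based).
#' @return `n x 3` centroid matrix with attributes `clusterId` and `size`.
#' @export
clusterCentroid <- function(sl, labeling, clusterId) {
  if (is(sl, "Tractogram")) sl <- streamlines(sl)
  members <- sl[clusterLabels(labeling) == clusterId]
  if (!length(members))
    stop(sprintf("cluster %d is empty", clusterId), call. = FALSE)
  cen <- tractCentroid(members)
  attr(cen, "clusterId") <- clusterId
  cen
}
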