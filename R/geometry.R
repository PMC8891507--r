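## Core streamline geometry: arc lengths, equispaced resampling, the MDF
## (minimum average direct-flip) distance, and the short-range "U"-shape
## filters. Streamlines are plain n x 3 numeric matrices in world mm.

checkStreamline <- function(s) {
  if (!is.matrix(s) || ncol(s) != 3L || nrow(s) < 2L)
    stop("a streamline must be an n x 3 matrix with n >= 2", call. = FALSE)
  if (!all(is.finite(s)))
    stop("streamline has non-finite coordinates", call. = FALSE)
  invisible(s)
}

#' Arc length of a streamline
#'
#' Sum of Euclidean distances between consecutive points, in mm.
#'
#' @param s an `n x 3` streamline matrix (world mm).
#' @return The polyline arc length L (mm).
#' @examples
#' arcLength(rbind(c(0, 0, 0), c(3, 4, 0)))  # 5
#' @export
arcLength <- function(s) {
  checkStreamline(s)
  d <- diff(s)
  sum(sqrt(rowSums(d * d)))
}

#' Endpoint (chord) distance of a streamline
#'
#' Euclidean distance between the two terminal points, in mm. Always
#' `<=` [arcLength()].
#'
#' @inheritParams arcLength
#' @return The endpoint distance D (mm).
#' @export
endpointDistance <- function(s) {
  checkStreamline(s)
  sqrt(sum((s[nrow(s), ] - s[1, ])^2))
}

#' Resample a streamline to n equispaced points
#'
#' Returns `n` points at arc-length positions `i * L / (n - 1)`,
#' `i = 0 ... n-1`, by linear interpolation along the polyline. Endpoints
#' are preserved exactly. This is the resampling applied before any MDF
#' distance computation (default `n = 20` samples, inclusive of endpoints).
#'
#' @inheritParams arcLength
#' @param n number of output points (>= 2).
#' @param index optional streamline index, used only in error messages.
#' @return An `n x 3` matrix of equispaced points.
#' @examples
#' resampleStreamline(rbind(c(0, 0, 0), c(19, 0, 0)), 20)
#' @export
resampleStreamline <- function(s, n = 20L, index = NA_integer_) {
  checkStreamline(s)
  if (n < 2L) stop("n must be >= 2", call. = FALSE)
  seg <- sqrt(rowSums(diff(s)^2))
  L <- sum(seg)
  if (L <= 0)
    stop(sprintf("degenerate streamline%s: zero arc length",
                 if (is.na(index)) "" else paste0(" ", index)), call. = FALSE)
  # drop zero-length segments so interpolation positions are strictly increasing
  keep <- c(TRUE, seg > 0)
  s <- s[keep, , drop = FALSE]
  cum <- c(0, cumsum(seg[seg > 0]))
  tgt <- seq(0, L, length.out = n)
  # segment index for each target position (clamped to the last segment)
  i <- findInterval(tgt, cum, rightmost.closed = TRUE)
  i[i >= length(cum)] <- length(cum) - 1L
  w <- (tgt - cum[i]) / (cum[i + 1L] - cum[i])
  out <- s[i, , drop = FALSE] * (1 - w) + s[i + 1L, , drop = FALSE] * w
  out[1, ] <- s[1, ]
  out[n, ] <- s[nrow(s), ]
  out
}

#' Resample every streamline of a tractogram
#'
#' @param t a [Tractogram-class].
#' @param n points per streamline.
#' @return A `Tractogram` whose streamlines all have `n` points.
#' @export
resampleTractogram <- function(t, n = 20L) {
  stopifnot(is(t, "Tractogram"))
  sl <- streamlines(t)
  out <- vector("list", length(sl))
  for (i in seq_along(sl)) out[[i]] <- resampleStreamline(sl[[i]], n, index = i)
  tractogram(out, refDim(t), refAffine(t))
}

## flatten a list of common-n streamlines to the layout the C++ kernels use
flattenStreamlines <- function(sl, npts = NULL) {
  if (!length(sl)) stop("empty streamline collection", call. = FALSE)
  ns <- vapply(sl, nrow, 0L)
  if (is.null(npts)) npts <- ns[1]
  if (!all(ns == npts))
    stop("streamlines must share a common point count", call. = FALSE)
  # layout [streamline][point][xyz]
  as.numeric(aperm(array(unlist(lapply(sl, t)), dim = c(3L, npts, length(sl))),
                   c(1L, 2L, 3L)))
}

#' MDF distance between two resampled streamlines
#'
#' Minimum average direct-flip distance: the mean point-to-point Euclidean
#' distance between two equally sampled streamlines, minimised over
#' reversing one streamline's point order. Symmetric, non-negative, zero
#' for identical or reversed-identical streamlines.
#'
#' @param a,b `n x 3` matrices with the same number of points.
#' @return MDF distance in mm.
#' @examples
#' a <- cbind(0:19, 0, 0); b <- cbind(0:19, 3, 0)
#' mdfDistance(a, b)           # 3
#' mdfDistance(a, a[20:1, ])   # 0 (flip invariance)
#' @export
mdfDistance <- function(a, b) {
  checkStreamline(a); checkStreamline(b)
  n <- nrow(a)
  if (nrow(b) != n)
    stop("MDF distance requires equal point counts", call. = FALSE)
  dd <- mean(sqrt(rowSums((a - b)^2)))
  df <- mean(sqrt(rowSums((a - b[n:1, , drop = FALSE])^2)))
  min(dd, df)
}

#' Pairwise MDF distance matrix
#'
#' @param sl list of `n x 3` resampled streamline matrices (common n), or a
#'   [Tractogram-class] of resampled streamlines.
#' @return Symmetric matrix of MDF distances (mm) with zero diagonal.
#' @export
mdfDistanceMatrix <- function(sl) {
  if (is(sl, "Tractogram")) sl <- streamlines(sl)
  if (length(sl) < 2L) stop("need at least 2 streamlines", call. = FALSE)
  npts <- nrow(sl[[1]])
  .mdf_matrix_cpp(flattenStreamlines(sl, npts), npts, length(sl))
}

#' Test whether a streamline is "U"-shaped
#'
#' A streamline is taken as a short-range U-fiber when its endpoint distance
#' is below one third of its arc length (`D < L / pi`) and its length lies
#' within `[minLen, maxLen]` (defaults 20 and 80 mm). The bounds are applied
#' to the arc length `L` by default; set `boundOn = "endpoint"` to bound the
#' chord `D` instead.
#'
#' @inheritParams arcLength
#' @param minLen,maxLen length bounds in mm.
#' @param boundOn `"length"` (default) to bound L, `"endpoint"` to bound D.
#' @return logical.
#' @export
isUShaped <- function(s, minLen = 20, maxLen = 80,
                      boundOn = c("length", "endpoint")) {
  boundOn <- match.arg(boundOn)
  stopifnot(minLen > 0, minLen < maxLen)
  L <- arcLength(s)
  D <- endpointDistance(s)
  bounded <- if (boundOn == "length") L else D
  (D < L / pi) && bounded >= minLen && bounded <= maxLen
}

#' Test whether a streamline crosses the hemispheric midline
#'
#' TRUE iff any two points lie strictly on opposite sides of the sagittal
#' plane `x = midlineX`. Points exactly on the plane belong to neither side.
#'
#' @inheritParams arcLength
#' @param midlineX midline plane position (mm), default 0.
#' @return logical.
#' @export
crossesMidline <- function(s, midlineX = 0) {
  checkStreamline(s)
  any(s[, 1] > midlineX) && any(s[, 1] < midlineX)
}

#' Extract U-shaped, non-crossing streamlines from a tractogram
#'
#' Keeps streamlines that pass [isUShaped()] and do not cross the midline,
#' mirroring how superficial white matter streamlines are pulled out of
#' whole-brain tractography before their own clustering pass.
#'
#' @param t a [Tractogram-class].
#' @param midlineX midline plane (mm).
#' @param minLen,maxLen,boundOn passed to [isUShaped()].
#' @return list with `tractogram` (the survivors) and `indices` (their
#'   original positions in `t`).
#' @export
filterUShaped <- function(t, midlineX = 0, minLen = 20, maxLen = 80,
                          boundOn = c("length", "endpoint")) {
  stopifnot(is(t, "Tractogram"), nStreamlines(t) > 0L)
  boundOn <- match.arg(boundOn)
  keep <- vapply(streamlines(t), function(s)
    isUShaped(s, minLen, maxLen, boundOn) && !crossesMidline(s, midlineX),
    logical(1))
  idx <- which(keep)
  list(tractogram = tractogram(streamlines(t)[idx], refDim(t), refAffine(t)),
       indices = idx)
}
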