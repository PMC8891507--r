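#' @import methods
#' @importFrom stats sd qf pf quantile rnorm runif setNames cor p.adjust
#' @importFrom utils write.table read.table combn
#' @useDynLib tractreli, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

## A streamline is an n x 3 numeric matrix of world-space coordinates (mm).
## Tractograms carry the voxel grid the streamlines were tracked in so that
## density maps and scalar sampling can relate world space back to voxels.

#' Tractogram: a set of streamlines plus their spatial reference
#'
#' A `Tractogram` holds a collection of streamlines (each an `n x 3` numeric
#' matrix of world-space coordinates in millimetres) together with the voxel
#' grid dimensions and the 4x4 voxel-to-world affine of the image space the
#' streamlines live in. All streamlines of one object share this reference.
#'
#' @slot streamlines list of numeric matrices, one per streamline, each with
#'   3 columns (x, y, z in mm) and at least 2 rows.
#' @slot refDim integer vector of length 3, voxel grid dimensions.
#' @slot refAffine 4x4 numeric voxel-to-world affine (mm); must be invertible.
#'
#' @seealso [tractogram()], [streamlines()], [readTck()], [readTrk()]
#' @export
setClass("Tractogram",
  representation(streamlines = "list", refDim = "integer", refAffine = "matrix"))

setValidity("Tractogram", function(object) {
  msgs <- character()
  if (length(object@refDim) != 3L || any(object@refDim < 1L))
    msgs <- c(msgs, "refDim must be 3 positive integers")
  if (!all(dim(object@refAffine) == c(4L, 4L)))
    msgs <- c(msgs, "refAffine must be a 4x4 matrix")
  else if (abs(det(object@refAffine)) < .Machine$double.eps * 100)
    msgs <- c(msgs, "refAffine must be invertible")
  for (i in seq_along(object@streamlines)) {
    s <- object@streamlines[[i]]
    if (!is.matrix(s) || ncol(s) != 3L || nrow(s) < 2L) {
      msgs <- c(msgs, sprintf("streamline %d is not an n x 3 matrix with n >= 2", i))
      break
    }
    if (!all(is.finite(s))) {
      msgs <- c(msgs, sprintf("streamline %d has non-finite coordinates", i))
      break
    }
  }
  if (length(msgs)) msgs else TRUE
})

#' Construct a Tractogram
#'
#' @param streamlines list of `n x 3` numeric matrices (world mm).
#' @param refDim integer vector of length 3: voxel grid dimensions.
#' @param refAffine 4x4 voxel-to-world affine. Voxel convention is 0-based:
#'   world = affine %*% c(i, j, k, 1).
#' @return A [Tractogram-class] object.
#' @examples
#' t <- tractogram(list(cbind(0:4, 0, 0)), c(10L, 10L, 10L), diag(4))
#' nStreamlines(t)
#' @export
tractogram <- function(streamlines, refDim = c(100L, 100L, 100L),
                       refAffine = diag(4)) {
  streamlines <- lapply(streamlines, function(s) {
    s <- as.matrix(s)
    storage.mode(s) <- "double"
    dimnames(s) <- NULL
    s
  })
  new("Tractogram", streamlines = streamlines,
      refDim = as.integer(refDim), refAffine = as.matrix(refAffine))
}

#' Cluster labels over a tractogram
#'
#' Per-streamline integer cluster labels in `0 ... k-1`, with the sentinel
#' `-1` marking outliers or unassigned streamlines.
#'
#' @slot labels integer vector of per-streamline labels.
#' @slot k number of clusters.
#' @slot method clustering method, `"spectral"` or `"quickbundles"` (or
#'   `"planted"` for synthetic ground truth).
#' @slot params list of method parameters (kernel width, threshold, seed, ...).
#' @export
setClass("ClusterLabeling",
  representation(labels = "integer", k = "integer", method = "character",
                 params = "list"))

setValidity("ClusterLabeling", function(object) {
  msgs <- character()
  lab <- object@labels
  if (any(lab < -1L)) msgs <- c(msgs, "labels must be >= -1")
  if (any(lab >= object@k)) msgs <- c(msgs, "non-sentinel labels must be < k")
  if (length(object@k) != 1L || object@k < 1L) msgs <- c(msgs, "k must be a positive integer")
  if (length(msgs)) msgs else TRUE
})

clusterLabeling <- function(labels, k, method, params = list()) {
  new("ClusterLabeling", labels = as.integer(labels), k = as.integer(k),
      method = method, params = params)
}

#' Labeled tractography template
#'
#' Resampled template streamlines with their cluster labels and the
#' provenance (method, parameters, subsample seed) used to build them.
#' Propagating its labels to analysis tractograms is done with
#' [propagateLabels()].
#'
#' @slot streamlines list of resampled streamlines (common point count).
#' @slot labels integer cluster labels, one per streamline, no sentinels.
#' @slot nPoints resampling point count.
#' @slot provenance list: method, parameters, subsample seed.
#' @export
setClass("LabeledTemplate",
  representation(streamlines = "list", labels = "integer", nPoints = "integer",
                 provenance = "list"))

setValidity("LabeledTemplate", function(object) {
  msgs <- character()
  if (length(object@streamlines) != length(object@labels))
    msgs <- c(msgs, "labels and streamlines must have the same length")
  if (any(object@labels < 0L))
    msgs <- c(msgs, "template labels may not contain sentinels")
  if (length(object@streamlines) &&
      !all(vapply(object@streamlines, nrow, 0L) == object@nPoints))
    msgs <- c(msgs, "all template streamlines must have nPoints points")
  if (length(msgs)) msgs else TRUE
})

labeledTemplate <- function(streamlines, labels, nPoints, provenance = list()) {
  new("LabeledTemplate", streamlines = streamlines, labels = as.integer(labels),
      nPoints = as.integer(nPoints), provenance = provenance)
}

#' Tract density map (sparse)
#'
#' Per-voxel fraction of a tract's streamlines traversing the voxel. Stored
#' sparsely: `indices` are 1-based linear voxel indices into the grid and
#' `fractions` the corresponding values in (0, 1].
#'
#' @slot indices integer linear voxel indices (1-based, column-major).
#' @slot fractions numeric per-voxel fractions in (0, 1].
#' @slot refDim grid dimensions.
#' @slot refAffine 4x4 voxel-to-world affine.
#' @slot nStreamlines total streamlines in the tract.
#' @export
setClass("TractDensityMap",
  representation(indices = "integer", fractions = "numeric", refDim = "integer",
                 refAffine = "matrix", nStreamlines = "integer"))

setValidity("TractDensityMap", function(object) {
  msgs <- character()
  if (length(object@indices) != length(object@fractions))
    msgs <- c(msgs, "indices and fractions must have the same length")
  if (length(object@fractions) &&
      (min(object@fractions) <= 0 || max(object@fractions) > 1 + 1e-12))
    msgs <- c(msgs, "fractions must lie in (0, 1]")
  if (anyDuplicated(object@indices)) msgs <- c(msgs, "duplicate voxel indices")
  if (length(msgs)) msgs else TRUE
})

## ---- generics ----

#' @rdname Tractogram-class
#' @param x object
#' @export
setGeneric("streamlines", function(x) standardGeneric("streamlines"))
#' @rdname Tractogram-class
#' @export
setGeneric("nStreamlines", function(x) standardGeneric("nStreamlines"))
#' @rdname Tractogram-class
#' @export
setGeneric("refAffine", function(x) standardGeneric("refAffine"))
#' @rdname Tractogram-class
#' @export
setGeneric("refDim", function(x) standardGeneric("refDim"))
#' @rdname ClusterLabeling-class
#' @param x object
#' @export
setGeneric("clusterLabels", function(x) standardGeneric("clusterLabels"))
#' @rdname ClusterLabeling-class
#' @export
setGeneric("nClusters", function(x) standardGeneric("nClusters"))
#' @rdname ClusterLabeling-class
#' @export
setGeneric("clusterMethod", function(x) standardGeneric("clusterMethod"))

#' @rdname Tractogram-class
setMethod("streamlines", "Tractogram", function(x) x@streamlines)
#' @rdname Tractogram-class
setMethod("nStreamlines", "Tractogram", function(x) length(x@streamlines))
#' @rdname Tractogram-class
setMethod("refAffine", "Tractogram", function(x) x@refAffine)
#' @rdname Tractogram-class
setMethod("refDim", "Tractogram", function(x) x@refDim)
#' @rdname LabeledTemplate-class
setMethod("streamlines", "LabeledTemplate", function(x) x@streamlines)
#' @rdname LabeledTemplate-class
setMethod("nStreamlines", "LabeledTemplate", function(x) length(x@streamlines))
#' @rdname ClusterLabeling-class
setMethod("clusterLabels", "ClusterLabeling", function(x) x@labels)
#' @rdname LabeledTemplate-class
setMethod("clusterLabels", "LabeledTemplate", function(x) x@labels)
#' @rdname ClusterLabeling-class
setMethod("nClusters", "ClusterLabeling", function(x) x@k)
#' @rdname ClusterLabeling-class
setMethod("clusterMethod", "ClusterLabeling", function(x) x@method)

setMethod("show", "Tractogram", function(object) {
  ns <- length(object@streamlines)
  npts <- if (ns) range(vapply(object@streamlines, nrow, 0L)) else c(0L, 0L)
  cat(sprintf("Tractogram: %d streamlines (%d-%d points), grid %s\n",
              ns, npts[1], npts[2], paste(object@refDim, collapse = "x")))
})

setMethod("show", "ClusterLabeling", function(object) {
  cat(sprintf("ClusterLabeling (%s): %d streamlines, k = %d, %d outliers\n",
              object@method, length(object@labels), object@k,
              sum(object@labels == -1L)))
})

setMethod("show", "LabeledTemplate", function(object) {
  cat(sprintf("LabeledTemplate: %d streamlines x %d points, %d clusters\n",
              length(object@streamlines), object@nPoints,
              length(unique(object@labels))))
})

setMethod("show", "TractDensityMap", function(object) {
  cat(sprintf("TractDensityMap: %d streamlines over %d voxels (grid %s)\n",
              object@nStreamlines, length(object@indices),
              paste(object@refDim, collapse = "x")))
})

## Dense array view of a sparse density map.
#' @rdname TractDensityMap-class
#' @param x a `TractDensityMap`
#' @return `densityArray()` returns the dense 3D array of voxel fractions.
#' @export
densityArray <- function(x) {
  stopifnot(is(x, "TractDensityMap"))
  a <- array(0, dim = x@refDim)
  a[x@indices] <- x@fractions
  a
}
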