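## Template labeling: subsample a labeled template and propagate its cluster
## labels to analysis tractograms by maximum streamline similarity (minimum
## MDF distance).

#' Subsample a labeled template
#'
#' Uniform random subsample without replacement (the reference workflow
#' keeps 20,000 streamlines of the labeled whole-brain template before
#' propagation). A stratified option samples proportionally per cluster
#' with a minimum of one member each.
#'
#' @param template a [LabeledTemplate-class].
#' @param nKeep number of streamlines to keep.
#' @param seed integer seed (recorded in the provenance).
#' @param stratified logical; proportional per-cluster sampling.
#' @return A [LabeledTemplate-class] of `nKeep` streamlines.
#' @export
subsampleTemplate <- function(template, nKeep, seed = 1L, stratified = FALSE) {
  stopifnot(is(template, "LabeledTemplate"))
  n <- nStreamlines(template)
  if (nKeep > n)
    stop(sprintf("nKeep (%d) exceeds available streamlines (%d)", nKeep, n),
         call. = FALSE)
  labs <- clusterLabels(template)
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  set.seed(seed)
  if (stratified) {
    ids <- unique(labs)
    quota <- pmax(1L, round(nKeep * tabulate(match(labs, ids)) / n))
    keep <- unlist(lapply(seq_along(ids), function(i) {
      pool <- which(labs == ids[i])
      sample(pool, min(quota[i], length(pool)))
    }))
    if (length(keep) > nKeep) keep <- sort(sample(keep, nKeep)) else keep <- sort(keep)
  } else {
    keep <- sort(sample.int(n, nKeep))
  }
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  prov <- template@provenance
  prov$subsample <- list(nKeep = nKeep, seed = seed, stratified = stratified)
  labeledTemplate(streamlines(template)[keep], labs[keep],
                  template@nPoints, prov)
}

#' Propagate template labels to a target tractogram
#'
#' Every target streamline receives the cluster label of the template
#' streamline with the minimal MDF distance (maximum similarity). Ties go
#' to the lowest template index. With `maxDistance` set, targets farther
#' than the cutoff from every template streamline get the sentinel `-1`
#' (off by default, matching label propagation without rejection).
#'
#' @param template a [LabeledTemplate-class].
#' @param target a [Tractogram-class] or list of streamlines; resampled to
#'   the template's point count if needed.
#' @param maxDistance optional rejection distance in mm.
#' @return A [ClusterLabeling-class]; per-streamline nearest-template
#'   distances are in `params$distance`, nearest template indices in
#'   `params$templateIndex`.
#' @export
propagateLabels <- function(template, target, maxDistance = NULL) {
  stopifnot(is(template, "LabeledTemplate"))
  if (is(target, "Tractogram")) target <- streamlines(target)
  if (!length(target)) stop("empty target tractogram", call. = FALSE)
  npts <- template@nPoints
  if (any(vapply(target, nrow, 0L) != npts))
    target <- lapply(seq_along(target), function(i)
      resampleStreamline(target[[i]], npts, index = i))
  nn <- .mdf_nearest_cpp(flattenStreamlines(target, npts),
                         flattenStreamlines(streamlines(template), npts),
                         npts, length(target), nStreamlines(template))
  labs <- clusterLabels(template)[nn$index]
  if (!is.null(maxDistance)) labs[nn$distance > maxDistance] <- -1L
  clusterLabeling(labs, max(clusterLabels(template)) + 1L, "propagated",
                  list(distance = nn$distance, templateIndex = nn$index,
                       maxDistance = maxDistance))
}
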