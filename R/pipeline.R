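## Pipeline orchestration: run configuration (defaults = the reference
## workflow's parameters), template building (resample -> optional U-shape
## filter -> MDF distances -> outlier pruning -> clustering -> labeled
## subsample), reliability analysis over a cohort, and the monolithic
## run-all that namespaces outputs per clustering method.

#' Run configuration
#'
#' Defaults follow the reference template-based clustering workflow:
#' 20 samples per streamline; whole-brain spectral clustering with k = 800
#' and an 8 mm Gaussian kernel (QuickBundles threshold 8 mm, cap 800);
#' U-shaped tract clustering with k = 500 and 6 mm kernel/threshold;
#' a 20,000-streamline labeled subsample for propagation; U-fiber length
#' bounds [20, 80] mm applied to arc length with `D < L/pi`.
#'
#' @param method `"spectral"`, `"quickbundles"` or `"both"`.
#' @param nSamples points per resampled streamline.
#' @param wholebrain,ushape named lists overriding the per-variant defaults
#'   (`k`, `sigma`, `threshold`, `maxClusters`; for ushape also `minLen`,
#'   `maxLen`, `boundOn`, `midlineX`, `enabled`).
#' @param subsampleSize labeled-template subsample size.
#' @param seed root seed for clustering and subsampling.
#' @param outDir output directory (`NULL` = return objects only).
#' @param paths named list of input paths (`template`, `subjects`,
#'   `volumes`, `labelVolume`) when running from files.
#' @param synthetic named list of [demoCohortSpec()] arguments when the
#'   cohort is generated rather than read.
#' @return list of class `"runConfig"`.
#' @export
runConfig <- function(method = c("both", "spectral", "quickbundles"),
                      nSamples = 20L,
                      wholebrain = list(), ushape = list(),
                      subsampleSize = 20000L, seed = 1L, outDir = NULL,
                      paths = list(), synthetic = NULL) {
  method <- match.arg(method)
  wb <- modifyList(list(k = 800L, sigma = 8, threshold = 8,
                        maxClusters = 800L), wholebrain)
  us <- modifyList(list(k = 500L, sigma = 6, threshold = 6,
                        maxClusters = 500L, minLen = 20, maxLen = 80,
                        boundOn = "length", midlineX = 0, enabled = TRUE),
                   ushape)
  structure(list(method = method, nSamples = as.integer(nSamples),
                 wholebrain = wb, ushape = us,
                 subsampleSize = as.integer(subsampleSize),
                 seed = as.integer(seed), outDir = outDir, paths = paths,
                 synthetic = synthetic),
            class = "runConfig")
}

#' Read/write a run configuration as YAML
#'
#' Round-trips losslessly: `readRunConfig(writeRunConfig(cfg, f))` equals
#' `cfg`.
#'
#' @param config a [runConfig()].
#' @param file YAML path.
#' @export
writeRunConfig <- function(config, file) {
  yaml::write_yaml(unclass(config), file)
  invisible(file)
}

#' @rdname writeRunConfig
#' @export
readRunConfig <- function(file) {
  raw <- yaml::read_yaml(file)
  do.call(runConfig, raw[!vapply(raw, is.null, TRUE)])
}

clusterVariant <- function(resampled, method, pars, seed) {
  if (method == "spectral") {
    if (pars$k > length(resampled))
      stop(sprintf("k = %d exceeds the %d available streamlines",
                   pars$k, length(resampled)), call. = FALSE)
    dm <- mdfDistanceMatrix(resampled)
    keep <- removeOutliers(dm)
    aff <- gaussianAffinity(dm[keep, keep, drop = FALSE], pars$sigma)
    lab <- spectralCluster(aff, min(pars$k, length(keep)), seed = seed)
    list(keep = keep, labels = clusterLabels(lab))
  } else {
    dm <- mdfDistanceMatrix(resampled)
    keep <- removeOutliers(dm)
    qb <- quickBundles(resampled[keep], threshold = pars$threshold,
                       maxClusters = pars$maxClusters)
    list(keep = keep, labels = clusterLabels(qb$labeling))
  }
}

#' Build a labeled tractography template
#'
#' Resamples the template tractogram, optionally extracts U-shaped
#' streamlines, computes the MDF distance matrix, prunes outliers
#' (> 2 SD of the mean streamline distance), clusters with the requested
#' method, and subsamples the labeled result for propagation. Deterministic
#' given the configuration.
#'
#' @param config a [runConfig()].
#' @param template a [Tractogram-class].
#' @param method `"spectral"` or `"quickbundles"`.
#' @param variant `"wholebrain"` or `"ushape"`.
#' @param verbose log stage-level streamline counts.
#' @return A [LabeledTemplate-class].
#' @export
runTemplateBuild <- function(config, template,
                             method = c("spectral", "quickbundles"),
                             variant = c("wholebrain", "ushape"),
                             verbose = FALSE) {
  method <- match.arg(method)
  variant <- match.arg(variant)
  stopifnot(is(template, "Tractogram"), nStreamlines(template) > 0L)
  pars <- config[[variant]]
  say <- function(...) if (verbose) message(sprintf(...))
  say("[%s/%s] input: %d streamlines", method, variant, nStreamlines(template))
  if (variant == "ushape") {
    fl <- filterUShaped(template, midlineX = pars$midlineX,
                        minLen = pars$minLen, maxLen = pars$maxLen,
                        boundOn = pars$boundOn)
    template <- fl$tractogram
    say("[%s/%s] U-shape filter retained %d", method, variant,
        nStreamlines(template))
    if (nStreamlines(template) < 3L)
      stop("U-shape filter left fewer than 3 streamlines", call. = FALSE)
  }
  rt <- resampleTractogram(template, config$nSamples)
  cl <- clusterVariant(streamlines(rt), method, pars, config$seed)
  say("[%s/%s] outlier pruning retained %d", method, variant, length(cl$keep))
  full <- labeledTemplate(streamlines(rt)[cl$keep], cl$labels, config$nSamples,
                          list(method = method, variant = variant,
                               params = pars, seed = config$seed))
  nKeep <- min(config$subsampleSize, nStreamlines(full))
  subsampleTemplate(full, nKeep, seed = config$seed + 1L)
}

#' Reliability analysis of a cohort against a labeled template
#'
#' Per subject: resample, propagate template labels, and per tract compute
#' the centroid, sparse density map, along-tract scalar profile and
#' streamline count. Per tract: mean MDF distance to the cohort-average
#' centroid, mean pairwise wDSC, two-way random-effects absolute-agreement
#' ICC of the along-tract profiles, mean streamline count and CV. Tracts
#' absent in a subject are excluded from that subject's centroid, wDSC and
#' profile computations and tallied in the missing-tract report.
#'
#' @param config a [runConfig()].
#' @param template a [LabeledTemplate-class].
#' @param subjects list of [Tractogram-class], one per subject/session.
#' @param volumes list of 3D scalar arrays (e.g. FA), one per subject; may
#'   be `NULL` to skip profiles/ICC.
#' @param refAffine affine of the scalar volumes (defaults to the first
#'   subject's reference).
#' @return list with `table` (the reliability data.frame, one row per
#'   tract), `correlations` (from [metricCorrelations()]), `missing`
#'   (tract x subject absences), `labelings` (per-subject propagated
#'   labels).
#' @export
runReliability <- function(config, template, subjects, volumes = NULL,
                           refAffine = NULL) {
  stopifnot(is(template, "LabeledTemplate"), length(subjects) >= 2L)
  if (is.null(refAffine)) refAffine <- refAffine(subjects[[1]])
  nS <- length(subjects)
  tractIds <- sort(unique(clusterLabels(template)))
  labelings <- vector("list", nS)
  percen <- perden <- perprof <- vector("list", nS)
  counts <- matrix(0L, nS, length(tractIds),
                   dimnames = list(NULL, as.character(tractIds)))
  for (s in seq_len(nS)) {
    rt <- resampleTractogram(subjects[[s]], template@nPoints)
    lab <- propagateLabels(template, rt)
    labelings[[s]] <- lab
    sl <- streamlines(rt)
    cen <- den <- prof <- setNames(vector("list", length(tractIds)),
                                   as.character(tractIds))
    for (ti in seq_along(tractIds)) {
      id <- tractIds[ti]
      members <- sl[clusterLabels(lab) == id]
      counts[s, ti] <- length(members)
      if (!length(members)) next
      cen[[ti]] <- tractCentroid(members)
      den[[ti]] <- densityMap(members, refDim(subjects[[s]]),
                              refAffine(subjects[[s]]))
      if (!is.null(volumes))
        prof[[ti]] <- tractProfile(members, volumes[[s]], refAffine)
    }
    percen[[s]] <- cen; perden[[s]] <- den; perprof[[s]] <- prof
  }
  rows <- lapply(seq_along(tractIds), function(ti) {
    present <- which(counts[, ti] > 0L)
    cens <- lapply(percen[present], `[[`, ti)
    mdist <- mwdsc <- icc <- iccLo <- iccHi <- NA_real_
    if (length(present) >= 2L) {
      avg <- averageCentroid(cens)
      mdist <- mean(vapply(cens, centroidDistance, 0, avg = avg))
      mwdsc <- pairwiseWdscMean(lapply(perden[present], `[[`, ti))
      if (!is.null(volumes)) {
        pm <- do.call(rbind, lapply(perprof[present], `[[`, ti))
        ic <- iccAbsolute(pm)
        icc <- ic$icc; iccLo <- ic$lower; iccHi <- ic$upper
      }
    }
    data.frame(tract = tractIds[ti],
               mean_centroid_distance = mdist,
               mean_wdsc = mwdsc,
               icc = icc, icc_lower = iccLo, icc_upper = iccHi,
               mean_count = mean(counts[, ti]),
               cv = as.numeric(streamlineCV(counts[, ti])),
               n_subjects = length(present))
  })
  table <- do.call(rbind, rows)
  miss <- which(counts == 0L, arr.ind = TRUE)
  missing <- data.frame(tract = tractIds[miss[, 2]], subject = miss[, 1],
                        reason = rep("no_streamlines", nrow(miss)))
  correlations <- if (nrow(table) >= 4L && sum(stats::complete.cases(
    table[, c("mean_centroid_distance", "mean_wdsc", "icc", "mean_count",
              "cv")])) >= 4L)
    metricCorrelations(table[, c("mean_centroid_distance", "mean_wdsc",
                                 "icc", "mean_count", "cv")])
  else NULL
  list(table = table, correlations = correlations, missing = missing,
       labelings = labelings)
}

#' Compare per-tract metrics between the two clustering methods
#'
#' Unpaired two-sample t-tests per metric column (pooled-variance by
#' default, Welch optional).
#'
#' @param tableA,tableB reliability tables from [runReliability()].
#' @param welch use Welch's t instead of pooled variance.
#' @return data.frame with `metric`, `t`, `p`, `df`.
#' @export
compareMethods <- function(tableA, tableB, welch = FALSE) {
  metrics <- c("mean_centroid_distance", "mean_wdsc", "icc", "mean_count", "cv")
  rows <- lapply(metrics, function(m) {
    a <- tableA[[m]]; b <- tableB[[m]]
    a <- a[is.finite(a)]; b <- b[is.finite(b)]
    if (length(a) < 2L || length(b) < 2L ||
        (stats::sd(a) == 0 && stats::sd(b) == 0))
      return(data.frame(metric = m, t = NA_real_, p = NA_real_,
                        df = NA_real_))
    tt <- stats::t.test(a, b, var.equal = !welch)
    data.frame(metric = m, t = unname(tt$statistic), p = tt$p.value,
               df = unname(tt$parameter))
  })
  do.call(rbind, rows)
}

writeTsv <- function(df, file) {
  dir.create(dirname(file), recursive = TRUE, showWarnings = FALSE)
  write.table(format(df, digits = 15, trim = TRUE, scientific = FALSE),
              file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}

#' Run the full pipeline
#'
#' Loads or generates the cohort, builds whole-brain (and, when enabled,
#' U-shape) labeled templates for each requested clustering method, runs
#' the reliability analysis, and - when both methods run - the inter-method
#' comparison. With `outDir` set, writes per-method reliability and
#' correlation TSVs, the missing-tract report, and a provenance JSON
#' capturing the configuration and seeds.
#'
#' @param config a [runConfig()].
#' @param cohort optional cohort list as returned by [makeCohort()]; when
#'   `NULL`, built from `config$synthetic` or read from `config$paths`.
#' @return nested list: per method, per variant, the [runReliability()]
#'   output plus the labeled template; `comparison` when both methods ran.
#' @export
runAll <- function(config, cohort = NULL) {
  if (is.null(cohort)) {
    if (!is.null(config$synthetic)) {
      cohort <- makeCohort(do.call(demoCohortSpec, config$synthetic))
    } else {
      p <- config$paths
      stopifnot(!is.null(p$template), length(p$subjects) >= 2L)
      template <- readTck(p$template)
      subjects <- lapply(p$subjects, readTck)
      volumes <- NULL; va <- diag(4)
      if (!is.null(p$volumes)) {
        vols <- lapply(p$volumes, readNiftiVolume)
        volumes <- lapply(vols, `[[`, "data")
        va <- vols[[1]]$affine
        subjects <- lapply(subjects, function(t)
          tractogram(streamlines(t), dim(volumes[[1]]), va))
        template <- tractogram(streamlines(template), dim(volumes[[1]]), va)
      }
      cohort <- list(template = template, subjects = subjects,
                     volumes = volumes, refAffine = va,
                     refDim = refDim(template))
    }
  }
  methods <- if (config$method == "both") c("spectral", "quickbundles")
             else config$method
  variants <- c("wholebrain", if (isTRUE(config$ushape$enabled)) "ushape")
  out <- list()
  for (m in methods) {
    out[[m]] <- list()
    for (v in variants) {
      tmpl <- runTemplateBuild(config, cohort$template, m, v)
      subjects <- cohort$subjects
      if (v == "ushape") {
        us <- config$ushape
        subjects <- lapply(subjects, function(t)
          filterUShaped(t, midlineX = us$midlineX, minLen = us$minLen,
                        maxLen = us$maxLen, boundOn = us$boundOn)$tractogram)
      }
      rel <- runReliability(config, tmpl, subjects, cohort$volumes,
                            refAffine = cohort$refAffine)
      rel$template <- tmpl
      out[[m]][[v]] <- rel
      if (!is.null(config$outDir)) {
        d <- file.path(config$outDir, m)
        writeTsv(rel$table, file.path(d, paste0(v, "_reliability.tsv")))
        if (!is.null(rel$correlations))
          writeTsv(rel$correlations, file.path(d, paste0(v, "_correlations.tsv")))
        writeTsv(rel$missing, file.path(d, paste0(v, "_missing.tsv")))
        writeLabeledTemplate(tmpl, file.path(d, paste0(v, "_template")))
      }
    }
  }
  if (length(methods) == 2L) {
    out$comparison <- compareMethods(out[[1]]$wholebrain$table,
                                     out[[2]]$wholebrain$table)
    out$comparison_welch <- compareMethods(out[[1]]$wholebrain$table,
                                           out[[2]]$wholebrain$table,
                                           welch = TRUE)
  }
  if (!is.null(config$outDir)) {
    prov <- list(config = unclass(config),
                 package = as.character(utils::packageVersion("tractreli")),
                 rversion = R.version.string,
                 timestampFree = TRUE)
    jsonlite::write_json(prov, file.path(config$outDir, "provenance.json"),
                         auto_unbox = TRUE, digits = NA, null = "null",
                         force = TRUE)
    if (length(methods) == 2L)
      writeTsv(out$comparison, file.path(config$outDir, "method_comparison.tsv"))
  }
  out
}

#' Adjusted Rand index between two labelings
#'
#' Chance-corrected agreement between two partitions; 1 means identical
#' partitions up to relabeling. Used throughout the tests to compare
#' recovered clusters with planted bundle labels.
#'
#' @param a,b integer label vectors of equal length (sentinels compared
#'   as their own class).
#' @return ARI in [-1, 1].
#' @export
adjustedRandIndex <- function(a, b) {
  stopifnot(length(a) == length(b))
  tab <- table(a, b)
  ch2 <- function(x) x * (x - 1) / 2
  sij <- sum(ch2(tab))
  si <- sum(ch2(rowSums(tab)))
  sj <- sum(ch2(colSums(tab)))
  n2 <- ch2(length(a))
  expected <- si * sj / n2
  maxidx <- (si + sj) / 2
  if (maxidx == expected) return(1)
  (sij - expected) / (maxidx - expected)
}
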