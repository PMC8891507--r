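## Synthetic multi-subject tractography with planted ground truth: bundles
## built from parametric centroid curves (lines, circular arcs, cubic
## Beziers), per-streamline rigid dispersion, per-subject centroid jitter,
## session-varying counts, and a rendered scalar volume standing in for FA.
##
## Randomness policy: one root seed; every (subject, bundle) pair draws from
## its own stream derived by counter offsets, so adding a bundle or subject
## never perturbs the coordinates of existing ones.

deriveSeed <- function(root, subject, bundle) {
  as.integer((as.numeric(root) + 100003 * subject + 1009 * bundle) %% 2147483629)
}

withSeed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  set.seed(seed)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  expr
}

#' Specify a synthetic streamline bundle
#'
#' A bundle is a parametric centroid curve plus dispersion parameters. The
#' curve is a straight line (`start`, `end`), a circular arc (`center`,
#' `radius`, `arcFraction`, in-plane unit vectors `u`, `v`), or a cubic
#' Bezier (`control`, a 4 x 3 matrix). Each generated streamline is a dense
#' copy of the curve rigidly offset by an isotropic Gaussian translation
#' (`dispersionSd`), optionally with small independent per-point jitter
#' (`pointJitterSd`, default 0). Half the streamlines are emitted with
#' reversed point order to exercise orientation (flip) handling downstream.
#'
#' @param name bundle name.
#' @param kind `"line"`, `"arc"` or `"bezier"`.
#' @param params list of curve parameters (see above), lengths in mm.
#' @param nStreamlines streamlines per bundle.
#' @param dispersionSd per-streamline rigid offset SD in mm.
#' @param pointJitterSd per-point jitter SD in mm (default 0).
#' @param hemisphere `"left"`, `"right"` or `"crossing"` (annotation only).
#' @param nDense dense sample count of the centroid curve (>= 50).
#' @return list of class `"bundleSpec"`.
#' @export
bundleSpec <- function(name, kind = c("line", "arc", "bezier"), params,
                       nStreamlines = 100L, dispersionSd = 1,
                       pointJitterSd = 0, hemisphere = "left", nDense = 60L) {
  kind <- match.arg(kind)
  stopifnot(dispersionSd >= 0, pointJitterSd >= 0, nStreamlines >= 1L,
            nDense >= 50L)
  spec <- structure(list(name = name, kind = kind, params = params,
                         nStreamlines = as.integer(nStreamlines),
                         dispersionSd = dispersionSd,
                         pointJitterSd = pointJitterSd,
                         hemisphere = hemisphere, nDense = as.integer(nDense)),
                    class = "bundleSpec")
  L <- arcLength(centroidCurve(spec))
  if (L <= 0 || L > 300)
    stop(sprintf("bundle '%s': curve length %.1f mm outside (0, 300]", name, L),
         call. = FALSE)
  spec
}

#' Dense centroid curve of a bundle spec
#'
#' @param spec a [bundleSpec()].
#' @return `nDense x 3` matrix of curve points (world mm).
#' @export
centroidCurve <- function(spec) {
  t <- seq(0, 1, length.out = spec$nDense)
  p <- spec$params
  switch(spec$kind,
    line = {
      outer(1 - t, p$start) + outer(t, p$end)
    },
    arc = {
      u <- p$u / sqrt(sum(p$u^2)); v <- p$v / sqrt(sum(p$v^2))
      th0 <- if (is.null(p$startAngle)) 0 else p$startAngle
      th <- th0 + t * 2 * pi * p$arcFraction
      sweep(outer(cos(th), u) + outer(sin(th), v), 2L,
            rep(0, 3), `+`) * p$radius +
        matrix(p$center, spec$nDense, 3, byrow = TRUE)
    },
    bezier = {
      cp <- p$control
      b <- cbind((1 - t)^3, 3 * (1 - t)^2 * t, 3 * (1 - t) * t^2, t^3)
      b %*% cp
    })
}

#' Generate the streamlines of one bundle
#'
#' @param spec a [bundleSpec()].
#' @param seed integer seed.
#' @param nStreamlines override of the spec's count (used for
#'   session-varying counts).
#' @param offset additional rigid translation applied to the whole bundle
#'   (the per-subject centroid jitter).
#' @return list of `nDense x 3` streamline matrices; attribute `name`
#'   carries the planted bundle label.
#' @export
makeBundle <- function(spec, seed = 1L, nStreamlines = NULL, offset = c(0, 0, 0)) {
  stopifnot(inherits(spec, "bundleSpec"))
  n <- if (is.null(nStreamlines)) spec$nStreamlines else as.integer(nStreamlines)
  curve <- sweep(centroidCurve(spec), 2L, offset, `+`)
  nd <- nrow(curve)
  out <- withSeed(seed, {
    lapply(seq_len(n), function(i) {
      s <- sweep(curve, 2L, stats::rnorm(3, sd = spec$dispersionSd), `+`)
      if (spec$pointJitterSd > 0)
        s <- s + matrix(stats::rnorm(3 * nd, sd = spec$pointJitterSd), nd, 3)
      if (i %% 2L == 0L) s[nd:1, , drop = FALSE] else s
    })
  })
  attr(out, "name") <- spec$name
  out
}

#' Specify a U-shaped (superficial white matter) bundle
#'
#' Builds an arc-based [bundleSpec()] and validates at construction that its
#' centroid satisfies the U-fiber constraints: endpoint distance below one
#' third of the arc length (`D < L / pi`), arc length within [20, 80] mm,
#' and the whole curve strictly on one side of the midline plane `x = 0`.
#' Violations fail fast with an error rather than generating an unusable
#' bundle.
#'
#' @param name bundle name.
#' @param center arc center (world mm).
#' @param radius arc radius in mm.
#' @param arcFraction fraction of a full circle covered (default 0.75).
#' @param u,v orthogonal in-plane unit vectors (default sagittal plane).
#' @param startAngle initial angle in radians.
#' @param ... passed to [bundleSpec()] (`nStreamlines`, `dispersionSd`, ...).
#' @return a `"bundleSpec"`.
#' @examples
#' makeUBundle("u1", center = c(30, 0, 0), radius = 10)  # L ~ 47 mm, passes
#' @export
makeUBundle <- function(name, center, radius, arcFraction = 0.75,
                        u = c(0, 1, 0), v = c(0, 0, 1), startAngle = 0, ...) {
  spec <- bundleSpec(name, "arc",
                     list(center = center, radius = radius,
                          arcFraction = arcFraction, u = u, v = v,
                          startAngle = startAngle),
                     hemisphere = if (center[1] < 0) "left" else "right", ...)
  curve <- centroidCurve(spec)
  L <- arcLength(curve)
  D <- endpointDistance(curve)
  if (!(D < L / pi))
    stop(sprintf("U-bundle '%s': D = %.2f mm is not < L/pi = %.2f mm",
                 name, D, L / pi), call. = FALSE)
  if (L < 20 || L > 80)
    stop(sprintf("U-bundle '%s': arc length %.1f mm outside [20, 80] mm",
                 name, L), call. = FALSE)
  if (crossesMidline(curve) || any(curve[, 1] == 0))
    stop(sprintf("U-bundle '%s': centroid touches or crosses the midline", name),
         call. = FALSE)
  spec
}

#' Specify a synthetic multi-subject cohort
#'
#' @param bundles list of [bundleSpec()]s.
#' @param nSubjects number of subjects/sessions.
#' @param subjectJitterSd SD (mm) of the per-subject rigid translation
#'   applied to each bundle centroid.
#' @param countJitter fraction; per-subject counts are
#'   `round(n * (1 + U(-countJitter, countJitter)))`.
#' @param seed root seed; fixed seed implies byte-identical outputs.
#' @param refDim,refAffine voxel grid of the common space.
#' @param scalarField list describing the rendered scalar volume:
#'   `list(type = "constant", value = c)`,
#'   `list(type = "gradient", origin = o, slope = s, axis = 1)`
#'   (value = o + s * world coordinate along `axis`), or
#'   `list(type = "plateau", background = b, values = per-bundle values)`
#'   (voxels traversed by a bundle take its value; elsewhere background).
#' @return list of class `"cohortSpec"`.
#' @export
cohortSpec <- function(bundles, nSubjects = 15L, subjectJitterSd = 1,
                       countJitter = 0.1, seed = 42L,
                       refDim = c(80L, 96L, 80L),
                       refAffine = NULL,
                       scalarField = list(type = "plateau", background = 0.2,
                                          values = NULL)) {
  if (is.null(refAffine)) {
    refAffine <- diag(c(2, 2, 2, 1))
    refAffine[1:3, 4] <- -(refDim - 1) / 2 * 2
  }
  stopifnot(nSubjects >= 1L, subjectJitterSd >= 0, countJitter >= 0,
            countJitter < 1)
  structure(list(bundles = bundles, nSubjects = as.integer(nSubjects),
                 subjectJitterSd = subjectJitterSd, countJitter = countJitter,
                 seed = as.integer(seed), refDim = as.integer(refDim),
                 refAffine = refAffine, scalarField = scalarField),
            class = "cohortSpec")
}

renderScalarVolume <- function(spec, subjectStreamlines, subjectLabels) {
  sf <- spec$scalarField
  dm <- spec$refDim
  if (sf$type == "constant") return(array(sf$value, dim = dm))
  if (sf$type == "gradient") {
    ax <- if (is.null(sf$axis)) 1L else sf$axis
    idx <- array(0, dim = dm)
    # world coordinate of each voxel center along the chosen axis
    ii <- slice.index(idx, ax) - 1
    A <- spec$refAffine
    w <- A[ax, ax] * ii + A[ax, 4]
    return(array(sf$origin + sf$slope * w, dim = dm))
  }
  if (sf$type == "plateau") {
    vals <- sf$values
    nb <- length(spec$bundles)
    if (is.null(vals)) vals <- seq(0.3, 0.8, length.out = nb)
    vol <- array(sf$background, dim = dm)
    for (b in seq_len(nb)) {
      members <- subjectStreamlines[subjectLabels == (b - 1L)]
      if (!length(members)) next
      map <- densityMap(members, dm, spec$refAffine)
      vol[map@indices] <- vals[b]
    }
    return(vol)
  }
  stop("unknown scalarField type: ", sf$type, call. = FALSE)
}

#' Generate a synthetic cohort
#'
#' For each subject, every bundle is translated by a subject-specific
#' isotropic Gaussian offset (`subjectJitterSd`), its streamline count is
#' perturbed multiplicatively (`countJitter`), and a scalar volume is
#' rendered per `scalarField`. A jitter-free template tractogram (bundles at
#' their nominal position and counts) is returned alongside, with planted
#' labels for every streamline. Fully reproducible from the root seed.
#'
#' @param spec a [cohortSpec()].
#' @return list with elements `template` ([Tractogram-class]),
#'   `templateLabels` (planted [ClusterLabeling-class]), `subjects` (list of
#'   `Tractogram`s), `subjectLabels` (list of planted labelings), `volumes`
#'   (list of 3D arrays), `bundleNames`, `refDim`, `refAffine`, `spec`.
#' @export
makeCohort <- function(spec) {
  stopifnot(inherits(spec, "cohortSpec"))
  nb <- length(spec$bundles)
  buildSubject <- function(subj) {       # subj = 0 is the jitter-free template
    sl <- list(); labs <- integer()
    for (b in seq_len(nb)) {
      bs <- spec$bundles[[b]]
      # dispersion draws are seeded per bundle only: subjects differ by their
      # rigid jitter offsets and counts, so zero jitter means identical subjects
      sd0 <- deriveSeed(spec$seed, 0L, b)
      if (subj == 0L) {
        off <- c(0, 0, 0); cnt <- bs$nStreamlines
      } else {
        jit <- withSeed(deriveSeed(spec$seed, subj, 0L) + b, {
          list(off = stats::rnorm(3, sd = spec$subjectJitterSd),
               u = stats::runif(1, -spec$countJitter, spec$countJitter))
        })
        off <- jit$off
        cnt <- max(1L, as.integer(round(bs$nStreamlines * (1 + jit$u))))
      }
      bun <- makeBundle(bs, seed = sd0, nStreamlines = cnt, offset = off)
      sl <- c(sl, bun)
      labs <- c(labs, rep(b - 1L, length(bun)))
    }
    list(tract = tractogram(sl, spec$refDim, spec$refAffine),
         labels = clusterLabeling(labs, nb, "planted",
                                  list(seed = spec$seed, subject = subj)))
  }
  tmpl <- buildSubject(0L)
  subjects <- vector("list", spec$nSubjects)
  subjectLabels <- vector("list", spec$nSubjects)
  volumes <- vector("list", spec$nSubjects)
  for (s in seq_len(spec$nSubjects)) {
    sub <- buildSubject(s)
    subjects[[s]] <- sub$tract
    subjectLabels[[s]] <- sub$labels
    volumes[[s]] <- renderScalarVolume(spec, streamlines(sub$tract),
                                       clusterLabels(sub$labels))
  }
  list(template = tmpl$tract, templateLabels = tmpl$labels,
       subjects = subjects, subjectLabels = subjectLabels, volumes = volumes,
       bundleNames = vapply(spec$bundles, `[[`, "", "name"),
       refDim = spec$refDim, refAffine = spec$refAffine, spec = spec)
}

#' Default demonstration cohort
#'
#' Mirrors a multi-subject tractography study at toy scale: 15 subjects,
#' 12 bundles (8 long-range, 4 U-shaped, balanced across hemispheres),
#' 100-300 streamlines per bundle, a 2 mm isotropic 80 x 96 x 80 grid, and
#' a per-bundle plateau scalar field standing in for FA. Bundle separations
#' are large relative to the 1 mm dispersion so the planted partition is
#' recoverable by both clustering methods.
#'
#' @param nSubjects number of subjects (default 15).
#' @param subjectJitterSd per-subject centroid jitter SD in mm (default 1).
#' @param countJitter per-subject count perturbation fraction (default 0.1).
#' @param seed root seed.
#' @param dispersionSd within-bundle dispersion SD in mm (default 1).
#' @return a [cohortSpec()].
#' @export
demoCohortSpec <- function(nSubjects = 15L, subjectJitterSd = 1,
                           countJitter = 0.1, seed = 42L, dispersionSd = 1) {
  counts <- round(seq(100, 300, length.out = 12))
  lng <- list()
  # 8 long-range bundles: gentle cubic Bezier curves, 4 per hemisphere
  ys <- c(-45, -15, 15, 45)
  for (j in 1:4) {
    for (side in c(-1, 1)) {
      x <- side * (22 + 7 * j)
      cp <- rbind(c(x, ys[j], -40), c(x + side * 8, ys[j] - 8, -12),
                  c(x - side * 8, ys[j] + 8, 12), c(x, ys[j], 40))
      nm <- sprintf("long_%s_%d", if (side < 0) "L" else "R", j)
      lng[[nm]] <- bundleSpec(nm, "bezier", list(control = cp),
                              nStreamlines = counts[length(lng) + 1L],
                              dispersionSd = dispersionSd,
                              hemisphere = if (side < 0) "left" else "right")
    }
  }
  ush <- list()
  uy <- c(-55, 55); uz <- c(-28, 30)
  i <- 0L
  for (side in c(-1, 1)) {
    for (k in 1:2) {
      i <- i + 1L
      nm <- sprintf("u_%s_%d", if (side < 0) "L" else "R", k)
      ush[[nm]] <- makeUBundle(nm, center = c(side * 52, uy[k], uz[k]),
                               radius = 9 + k,
                               nStreamlines = counts[8L + i],
                               dispersionSd = dispersionSd)
    }
  }
  cohortSpec(c(lng, ush), nSubjects = nSubjects,
             subjectJitterSd = subjectJitterSd, countJitter = countJitter,
             seed = seed)
}
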