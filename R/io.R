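## Tractogram and volume I/O.
##
## TCK (MRtrix track file): text header terminated by "END\n", then
## little-endian float32 triplets; streamlines separated by a NaN triplet,
## file terminated by an Inf triplet. Coordinates are world mm already.
##
## TRK (TrackVis): fixed 1000-byte header (version 2) holding dim,
## voxel_size and the 4x4 vox_to_ras affine; points are stored in "voxmm"
## coordinates. On read the header affine is honored and points converted
## to world mm: rasmm = vox_to_ras %*% (voxmm / voxel_size - 0.5).
##
## NIfTI goes through RNifti; the sform carries the voxel-to-world affine.

#' Write a tractogram as a TCK file
#'
#' @param t a [Tractogram-class] (world mm).
#' @param file output path.
#' @return `file`, invisibly.
#' @export
writeTck <- function(t, file) {
  stopifnot(is(t, "Tractogram"))
  hdr0 <- paste0("mrtrix tracks\ndatatype: Float32LE\ncount: ",
                 nStreamlines(t), "\n")
  # the header length depends on the printed offset; fixed-point it, padding
  # with newlines if the digit count shrinks (bytes before offset are header)
  offset <- nchar(hdr0) + nchar("file: . \nEND\n") + 2L
  for (i in 1:6) {
    hdr <- paste0(hdr0, "file: . ", offset, "\nEND\n")
    if (nchar(hdr) == offset) break
    if (nchar(hdr) < offset) {
      hdr <- paste0(hdr, strrep("\n", offset - nchar(hdr)))
      break
    }
    offset <- nchar(hdr)
  }
  con <- file(file, "wb")
  on.exit(close(con))
  writeChar(hdr, con, eos = NULL)
  for (s in streamlines(t)) {
    writeBin(as.numeric(t(s)), con, size = 4L, endian = "little")
    writeBin(rep(NaN, 3), con, size = 4L, endian = "little")
  }
  writeBin(rep(Inf, 3), con, size = 4L, endian = "little")
  invisible(file)
}

#' Read a TCK file
#'
#' @param file path to a `.tck` file.
#' @param refDim,refAffine spatial reference to attach (TCK carries none).
#' @return A [Tractogram-class].
#' @export
readTck <- function(file, refDim = c(100L, 100L, 100L), refAffine = diag(4)) {
  raw <- readBin(file, "raw", n = file.size(file))
  end <- grepRaw("END\n", raw, fixed = TRUE)
  if (!length(end)) stop("not a TCK file (no END marker): ", file, call. = FALSE)
  hdr <- rawToChar(raw[seq_len(end - 1L)])
  if (!grepl("^mrtrix tracks", hdr))
    stop("not a TCK file (bad magic): ", file, call. = FALSE)
  m <- regmatches(hdr, regexec("file: \\. ([0-9]+)", hdr))[[1]]
  if (length(m) < 2L) stop("TCK header lacks a file offset: ", file, call. = FALSE)
  offset <- as.integer(m[2])
  vals <- readBin(raw[(offset + 1L):length(raw)], "numeric",
                  n = (length(raw) - offset) / 4L, size = 4L, endian = "little")
  pts <- matrix(vals, ncol = 3L, byrow = TRUE)
  isna <- is.nan(pts[, 1])
  isinf <- is.infinite(pts[, 1])
  stops <- which(isna | isinf)
  out <- list()
  start <- 1L
  for (stp in stops) {
    if (stp > start)
      out[[length(out) + 1L]] <- pts[start:(stp - 1L), , drop = FALSE]
    start <- stp + 1L
    if (isinf[stp]) break
  }
  tractogram(out, refDim, refAffine)
}

axcodes <- function(affine) {
  letters <- c("R", "A", "S"); inverse <- c("L", "P", "I")
  vapply(1:3, function(j) {
    col <- affine[1:3, j]
    ax <- which.max(abs(col))
    if (col[ax] >= 0) letters[ax] else inverse[ax]
  }, "")
}

#' Write a tractogram as a TRK file
#'
#' Points are converted from world mm to TrackVis voxmm using the
#' tractogram's reference affine, which is stored in the header.
#'
#' @inheritParams writeTck
#' @export
writeTrk <- function(t, file) {
  stopifnot(is(t, "Tractogram"))
  aff <- refAffine(t)
  vs <- sqrt(colSums(aff[1:3, 1:3]^2))
  inv <- solve(aff)
  con <- file(file, "wb")
  on.exit(close(con))
  writeChar("TRACK", con, nchars = 5L, eos = NULL); writeBin(raw(1L), con)
  writeBin(as.integer(refDim(t)), con, size = 2L, endian = "little")
  writeBin(as.numeric(vs), con, size = 4L, endian = "little")
  writeBin(rep(0, 3), con, size = 4L, endian = "little")        # origin
  writeBin(0L, con, size = 2L, endian = "little")               # n_scalars
  writeBin(raw(200L), con)                                      # scalar names
  writeBin(0L, con, size = 2L, endian = "little")               # n_properties
  writeBin(raw(200L), con)                                      # property names
  writeBin(as.numeric(t(aff)), con, size = 4L, endian = "little")  # vox_to_ras
  writeBin(raw(444L), con)                                      # reserved
  oc <- paste(axcodes(aff), collapse = "")
  writeChar(oc, con, nchars = 3L, eos = NULL); writeBin(raw(1L), con)
  writeBin(raw(4L), con)                                        # pad2
  writeBin(rep(0, 6), con, size = 4L, endian = "little")        # img orient
  writeBin(raw(2L), con)                                        # pad1
  writeBin(raw(6L), con)                                        # invert/swap
  writeBin(nStreamlines(t), con, size = 4L, endian = "little")  # n_count
  writeBin(2L, con, size = 4L, endian = "little")               # version
  writeBin(1000L, con, size = 4L, endian = "little")            # hdr_size
  for (s in streamlines(t)) {
    v <- cbind(s, 1) %*% t(inv)                 # world -> voxel
    voxmm <- sweep(v[, 1:3, drop = FALSE] + 0.5, 2L, vs, `*`)
    writeBin(nrow(s), con, size = 4L, endian = "little")
    writeBin(as.numeric(t(voxmm)), con, size = 4L, endian = "little")
  }
  invisible(file)
}

#' Read a TRK file
#'
#' The header affine is honored: points are returned in world mm.
#'
#' @param file path to a `.trk` file.
#' @return A [Tractogram-class] with the header's grid and affine.
#' @export
readTrk <- function(file) {
  con <- file(file, "rb")
  on.exit(close(con))
  magic <- readChar(con, 5L, useBytes = TRUE); readBin(con, "raw", 1L)
  if (magic != "TRACK") stop("not a TRK file: ", file, call. = FALSE)
  dm <- readBin(con, "integer", 3L, size = 2L, endian = "little")
  vs <- readBin(con, "numeric", 3L, size = 4L, endian = "little")
  readBin(con, "numeric", 3L, size = 4L, endian = "little")     # origin
  readBin(con, "integer", 1L, size = 2L, endian = "little")     # n_scalars
  readBin(con, "raw", 200L)
  readBin(con, "integer", 1L, size = 2L, endian = "little")     # n_properties
  readBin(con, "raw", 200L)
  aff <- matrix(readBin(con, "numeric", 16L, size = 4L, endian = "little"),
                4L, 4L, byrow = TRUE)
  readBin(con, "raw", 444L + 4L + 4L + 24L + 2L + 6L)
  nc <- readBin(con, "integer", 1L, size = 4L, endian = "little")
  readBin(con, "integer", 2L, size = 4L, endian = "little")     # version, hdr
  out <- list()
  repeat {
    np <- readBin(con, "integer", 1L, size = 4L, endian = "little")
    if (!length(np)) break
    voxmm <- matrix(readBin(con, "numeric", 3L * np, size = 4L,
                            endian = "little"), np, 3L, byrow = TRUE)
    vox <- sweep(voxmm, 2L, vs, `/`) - 0.5
    world <- cbind(vox, 1) %*% t(aff)
    out[[length(out) + 1L]] <- world[, 1:3, drop = FALSE]
    if (nc > 0L && length(out) >= nc) break
  }
  tractogram(out, dm, aff)
}

#' Read/write scalar or label NIfTI volumes
#'
#' Thin wrappers over RNifti keeping the voxel-to-world affine explicit.
#'
#' @param volume 3D numeric array.
#' @param refAffine 4x4 voxel-to-world affine (stored as the sform).
#' @param file path (`.nii` or `.nii.gz`).
#' @return `readNiftiVolume()` returns `list(data, affine)`.
#' @export
writeNiftiVolume <- function(volume, refAffine, file) {
  img <- RNifti::asNifti(volume)
  RNifti::sform(img) <- structure(refAffine, code = 2L)
  RNifti::writeNifti(img, file)
  invisible(file)
}

#' @rdname writeNiftiVolume
#' @export
readNiftiVolume <- function(file) {
  img <- RNifti::readNifti(file)
  aff <- unclass(RNifti::xform(img))
  attributes(aff) <- list(dim = dim(aff))
  list(data = array(as.numeric(img), dim = dim(img)), affine = aff)
}

#' Serialize cluster labelings
#'
#' Labels go to a two-column TSV (`streamline_index`, 0-based, and
#' `cluster_label`) with a JSON sidecar recording method and parameters.
#'
#' @param labeling a [ClusterLabeling-class].
#' @param file TSV path; the sidecar is written next to it as `.json`.
#' @return `readLabeling()` returns a [ClusterLabeling-class].
#' @export
writeLabeling <- function(labeling, file) {
  stopifnot(is(labeling, "ClusterLabeling"))
  df <- data.frame(streamline_index = seq_along(clusterLabels(labeling)) - 1L,
                   cluster_label = clusterLabels(labeling))
  write.table(df, file, sep = "\t", quote = FALSE, row.names = FALSE)
  side <- sub("\\.tsv$", ".json", file)
  meta <- c(list(method = clusterMethod(labeling), k = nClusters(labeling)),
            labeling@params[!vapply(labeling@params, is.null, TRUE)])
  meta <- meta[!vapply(meta, function(x) is.numeric(x) && length(x) > 50, TRUE)]
  jsonlite::write_json(meta, side, auto_unbox = TRUE, digits = NA)
  invisible(file)
}

#' @rdname writeLabeling
#' @export
readLabeling <- function(file) {
  df <- read.table(file, sep = "\t", header = TRUE)
  side <- sub("\\.tsv$", ".json", file)
  meta <- if (file.exists(side)) jsonlite::read_json(side, simplifyVector = TRUE)
          else list(method = "unknown", k = max(df$cluster_label) + 1L)
  clusterLabeling(df$cluster_label[order(df$streamline_index)],
                  k = meta$k, method = meta$method,
                  params = meta[setdiff(names(meta), c("method", "k"))])
}

#' Persist and load labeled templates
#'
#' A template directory holds `template.tck` (resampled streamlines),
#' `labels.tsv` (+ JSON sidecar) and `provenance.json`.
#'
#' @param template a [LabeledTemplate-class].
#' @param dir directory (created if needed).
#' @return `readLabeledTemplate()` returns a [LabeledTemplate-class].
#' @export
writeLabeledTemplate <- function(template, dir) {
  stopifnot(is(template, "LabeledTemplate"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  writeTck(tractogram(streamlines(template)), file.path(dir, "template.tck"))
  writeLabeling(clusterLabeling(clusterLabels(template),
                                max(clusterLabels(template)) + 1L,
                                "template"),
                file.path(dir, "labels.tsv"))
  jsonlite::write_json(c(template@provenance, list(nPoints = template@nPoints)),
                       file.path(dir, "provenance.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @rdname writeLabeledTemplate
#' @export
readLabeledTemplate <- function(dir) {
  t <- readTck(file.path(dir, "template.tck"))
  lab <- readLabeling(file.path(dir, "labels.tsv"))
  prov <- jsonlite::read_json(file.path(dir, "provenance.json"),
                              simplifyVector = TRUE)
  np <- prov$nPoints
  prov$nPoints <- NULL
  labeledTemplate(streamlines(t), clusterLabels(lab), np, prov)
}
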