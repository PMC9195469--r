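#' Two-channel fluorescence image container
#'
#' @param nuclear Numeric matrix of nuclear-stain intensities (e.g. DAPI).
#' @param marker Numeric matrix of marker intensities (e.g. PI, EdU,
#'   HIF1a), same shape.
#' @return A `two_channel_image` (list of the two matrices).
#' @export
two_channel_image <- function(nuclear, marker) {
  if (!is.matrix(nuclear) || !is.matrix(marker))
    abort("channels must be numeric matrices.")
  if (!identical(dim(nuclear), dim(marker)))
    abort("channels must share the same shape.")
  if (any(!is.finite(nuclear)) || any(!is.finite(marker)))
    abort("intensities must be finite.")
  if (min(nuclear) < 0 || min(marker) < 0)
    abort("intensities must be >= 0.")
  structure(list(nuclear = nuclear, marker = marker),
            class = "two_channel_image")
}

#' Otsu threshold of an intensity image
#'
#' Builds a 256-bin histogram over the observed intensity range and returns
#' the threshold maximizing the between-class variance; pixels strictly
#' above the threshold are foreground. Invariant (up to bin quantization)
#' under affine intensity rescaling.
#'
#' @param channel Numeric matrix with at least 2 distinct values.
#' @param levels Number of histogram bins (default 256).
#' @return The numeric threshold. Use [otsu_mask()] for the binary mask.
#' @export
otsu_threshold <- function(channel, levels = 256) {
  v <- as.vector(channel)
  rng <- range(v)
  if (rng[1] == rng[2]) abort("constant image: no threshold exists.")
  breaks <- seq(rng[1], rng[2], length.out = levels + 1)
  bin <- pmin(pmax(findInterval(v, breaks, rightmost.closed = TRUE), 1),
              levels)
  counts <- tabulate(bin, nbins = levels)
  p <- counts / length(v)
  mids <- (breaks[-1] + breaks[-(levels + 1)]) / 2
  w0 <- cumsum(p)
  mu0 <- cumsum(p * mids)
  muT <- mu0[levels]
  # between-class variance for splitting after bin k (k = 1..levels-1)
  k <- seq_len(levels - 1)
  sb2 <- (muT * w0[k] - mu0[k])^2 / (w0[k] * (1 - w0[k]))
  sb2[!is.finite(sb2)] <- -Inf
  kstar <- which.max(sb2)
  breaks[kstar + 1]  # upper edge of the background class
}

#' @param ... Passed to [otsu_threshold()].
#' @rdname otsu_threshold
#' @return `otsu_mask()` returns a logical matrix with the resolved
#'   threshold attached as attribute `"threshold"`.
#' @export
otsu_mask <- function(channel, ...) {
  th <- otsu_threshold(channel, ...)
  structure(channel > th, threshold = th)
}

# 8-connected labeling of a logical mask via graph components
label_components <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  fg <- which(mask)
  lab <- matrix(0L, nr, nc)
  if (length(fg) == 0) return(lab)
  vid <- integer(nr * nc)
  vid[fg] <- seq_along(fg)
  row_i <- ((fg - 1L) %% nr) + 1L
  col_i <- ((fg - 1L) %/% nr) + 1L
  edges <- list()
  # neighbours already visited in raster order: left, up, up-left, up-right
  for (off in list(c(0L, -1L), c(-1L, 0L), c(-1L, -1L), c(-1L, 1L))) {
    ri <- row_i + off[1]; ci <- col_i + off[2]
    ok <- ri >= 1L & ri <= nr & ci >= 1L & ci <= nc
    nb <- (ci[ok] - 1L) * nr + ri[ok]
    has <- vid[nb] > 0L
    edges[[length(edges) + 1L]] <-
      rbind(vid[fg[ok]][has], vid[nb][has])
  }
  em <- do.call(cbind, edges)
  g <- igraph::make_graph(edges = as.vector(em), n = length(fg),
                          directed = FALSE)
  comp <- igraph::components(g)$membership
  lab[fg] <- comp
  lab
}

#' Count nuclei in a binary mask
#'
#' Labels 8-connected foreground components and discards components smaller
#' than `min_area` pixels (noise specks).
#'
#' @param mask Logical matrix (e.g. from [otsu_mask()]).
#' @param min_area Minimum component area in pixels (default 20).
#' @return A tibble with one row per retained nucleus: `label`, `area`,
#'   `centroid_row`, `centroid_col`; the relabelled integer label matrix is
#'   attached as attribute `"label_matrix"`.
#' @export
count_nuclei <- function(mask, min_area = 20) {
  if (!is.logical(mask)) abort("`mask` must be a logical matrix.")
  lab <- label_components(mask)
  if (max(lab) == 0) {
    out <- tibble(label = integer(), area = integer(),
                  centroid_row = numeric(), centroid_col = numeric())
    return(structure(out, label_matrix = lab))
  }
  areas <- tabulate(lab[lab > 0])
  keep <- which(areas >= min_area)
  relab <- integer(length(areas))
  relab[keep] <- seq_along(keep)
  new_lab <- lab
  new_lab[lab > 0] <- relab[lab[lab > 0]]
  if (length(keep) == 0) {
    out <- tibble(label = integer(), area = integer(),
                  centroid_row = numeric(), centroid_col = numeric())
    return(structure(out, label_matrix = new_lab))
  }
  idx <- which(new_lab > 0)
  l <- new_lab[idx]
  ri <- ((idx - 1L) %% nrow(mask)) + 1L
  ci <- ((idx - 1L) %/% nrow(mask)) + 1L
  out <- tibble(label = seq_along(keep),
                area = as.integer(areas[keep]),
                centroid_row = as.numeric(tapply(ri, l, mean)),
                centroid_col = as.numeric(tapply(ci, l, mean)))
  structure(out, label_matrix = new_lab)
}

#' Marker-positive nucleus percentage (PI, EdU, ...)
#'
#' Segments nuclei on the nuclear channel (Otsu threshold + 8-connected
#' components), then calls a nucleus marker-positive when the mean marker
#' intensity over its pixels exceeds the cutoff. With `cutoff = "otsu"` the
#' cutoff is resolved on the marker channel and echoed in the result so the
#' same numeric value can be held fixed across images of a series. Images
#' with zero segmented nuclei yield an undefined (NA) percentage, never 0%.
#'
#' @param image A [two_channel_image()].
#' @param cutoff Numeric marker-intensity cutoff, or `"otsu"`.
#' @param min_area Minimum nucleus area in pixels (default 20).
#' @return A one-row tibble: `total_nuclei`, `positive_nuclei`,
#'   `percent_positive`, `cutoff`, `undefined`. Per-nucleus detail
#'   (centroids, areas, mean marker intensity, positivity) is attached as
#'   attribute `"per_nucleus"`.
#' @export
percent_positive <- function(image, cutoff = "otsu", min_area = 20) {
  stopifnot(inherits(image, "two_channel_image"))
  mask <- otsu_mask(image$nuclear)
  nuc <- count_nuclei(mask, min_area = min_area)
  if (identical(cutoff, "otsu")) {
    cutoff <- if (min(image$marker) == max(image$marker)) Inf
    else otsu_threshold(image$marker)
  }
  if (nrow(nuc) == 0) {
    return(tibble(total_nuclei = 0L, positive_nuclei = 0L,
                  percent_positive = NA_real_, cutoff = cutoff,
                  undefined = TRUE))
  }
  lab <- attr(nuc, "label_matrix")
  idx <- which(lab > 0)
  mean_marker <- as.numeric(tapply(image$marker[idx], lab[idx], mean))
  nuc$mean_marker <- mean_marker
  nuc$positive <- mean_marker > cutoff
  out <- tibble(total_nuclei = nrow(nuc),
                positive_nuclei = sum(nuc$positive),
                percent_positive = 100 * sum(nuc$positive) / nrow(nuc),
                cutoff = cutoff, undefined = FALSE)
  structure(out, per_nucleus = nuc)
}

#' @rdname percent_positive
#' @details `percent_proliferating()` is the identical computation with the
#'   marker channel read as EdU; the returned percentage is the fraction of
#'   proliferating (EdU+/DAPI+) cells.
#' @export
percent_proliferating <- percent_positive

#' Nuclear-normalized mean marker intensity
#'
#' Whole-frame mean marker intensity divided by whole-frame mean nuclear
#' intensity, the reduction used for HIF1a quantification. Invariant to a
#' common gain applied to both channels.
#'
#' @param image A [two_channel_image()].
#' @return The intensity ratio (scalar).
#' @export
mean_intensity_ratio <- function(image) {
  stopifnot(inherits(image, "two_channel_image"))
  mn <- mean(image$nuclear)
  if (mn == 0) abort("zero mean nuclear intensity.")
  mean(image$marker) / mn
}

#' Write / read a two-channel image as a channel-major multi-page TIFF
#'
#' Intensities are stored as 32-bit floats; page 1 is the nuclear channel,
#' page 2 the marker channel.
#'
#' @param image A [two_channel_image()].
#' @param path File path.
#' @export
write_two_channel_tiff <- function(image, path) {
  stopifnot(inherits(image, "two_channel_image"))
  tiff::writeTIFF(list(image$nuclear, image$marker), path,
                  bits.per.sample = 32L, reduce = FALSE)
  invisible(path)
}

#' @rdname write_two_channel_tiff
#' @export
read_two_channel_tiff <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE)
  if (length(pages) < 2) abort("TIFF must contain 2 pages (channels).")
  two_channel_image(pages[[1]], pages[[2]])
}
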