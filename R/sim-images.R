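#' Configuration for synthetic two-channel nuclei images
#'
#' @param width,height Image size in pixels.
#' @param n_nuclei Number of nuclei to place.
#' @param positive_fraction Fraction of nuclei that are marker-positive,
#'   in `[0, 1]`.
#' @param blob_sigma Gaussian blob standard deviation, pixels.
#' @param min_separation Minimum centre-to-centre distance between nuclei,
#'   pixels.
#' @param background_sd Gaussian background noise SD (intensity units;
#'   blob peak amplitude is 1).
#' @param seed Integer seed.
#' @return An `image_sim_config` list, validated.
#' @export
image_sim_config <- function(width = 384, height = 384, n_nuclei = 100,
                             positive_fraction = 0.4, blob_sigma = 3,
                             min_separation = 12, background_sd = 0.01,
                             seed = NULL) {
  if (positive_fraction < 0 || positive_fraction > 1)
    abort("`positive_fraction` must lie in [0, 1].")
  if (n_nuclei < 0) abort("`n_nuclei` must be >= 0.")
  if (blob_sigma <= 0 || min_separation < 0 || background_sd < 0)
    abort("invalid blob/separation/noise parameter.")
  structure(list(width = as.integer(width), height = as.integer(height),
                 n_nuclei = as.integer(n_nuclei),
                 positive_fraction = positive_fraction,
                 blob_sigma = blob_sigma, min_separation = min_separation,
                 background_sd = background_sd, seed = seed),
            class = "image_sim_config")
}

place_centers <- function(cfg) {
  margin <- ceiling(3 * cfg$blob_sigma) + 1
  if (cfg$n_nuclei == 0) return(cbind(numeric(0), numeric(0)))
  max_tries <- 200L * cfg$n_nuclei
  rows <- numeric(cfg$n_nuclei); cols <- numeric(cfg$n_nuclei)
  placed <- 0L; tries <- 0L
  min2 <- cfg$min_separation^2
  while (placed < cfg$n_nuclei) {
    tries <- tries + 1L
    if (tries > max_tries)
      abort("could not place all nuclei at the requested min_separation.")
    r <- runif(1, margin, cfg$height - margin)
    c <- runif(1, margin, cfg$width - margin)
    if (placed > 0) {
      d2 <- (rows[seq_len(placed)] - r)^2 + (cols[seq_len(placed)] - c)^2
      if (min(d2) < min2) next
    }
    placed <- placed + 1L
    rows[placed] <- r; cols[placed] <- c
  }
  cbind(rows, cols)
}

render_blobs <- function(centers, cfg) {
  img <- matrix(0, cfg$height, cfg$width)
  if (nrow(centers) == 0) return(img)
  hw <- ceiling(4 * cfg$blob_sigma)
  for (i in seq_len(nrow(centers))) {
    r0 <- centers[i, 1]; c0 <- centers[i, 2]
    rr <- max(1, floor(r0 - hw)):min(cfg$height, ceiling(r0 + hw))
    cc <- max(1, floor(c0 - hw)):min(cfg$width, ceiling(c0 + hw))
    patch <- outer(exp(-(rr - r0)^2 / (2 * cfg$blob_sigma^2)),
                   exp(-(cc - c0)^2 / (2 * cfg$blob_sigma^2)))
    img[rr, cc] <- img[rr, cc] + patch
  }
  img
}

#' Generate a synthetic two-channel nuclei image with known counts
#'
#' Channel 1 (nuclear) holds `n_nuclei` symmetric Gaussian blobs of peak
#' amplitude 1 at centre-to-centre distance >= `min_separation`; channel 2
#' (marker) holds blobs at `round(positive_fraction * n_nuclei)` of the
#' same centres (perfect colocalization, mirroring marker+/nuclear+ overlap
#' counting). Gaussian background noise is added to both channels and
#' intensities are clipped to `[0, 1]` (detector saturation). The
#' ground-truth counts are attached and retrievable via [ground_truth()]
#' and are exact by construction, irrespective of noise.
#'
#' @param cfg An [image_sim_config()].
#' @return A [two_channel_image()] with attribute `ground_truth`: a one-row
#'   tibble `total_nuclei`, `positive_nuclei`, `percent_positive`.
#' @export
generate_nuclei_image <- function(cfg) {
  stopifnot(inherits(cfg, "image_sim_config"))
  run_seeded(cfg$seed, {
    centers <- place_centers(cfg)
    n_pos <- round(cfg$positive_fraction * cfg$n_nuclei)
    pos_idx <- if (n_pos > 0) sample(cfg$n_nuclei, n_pos) else integer(0)
    nuclear <- render_blobs(centers, cfg)
    marker <- render_blobs(centers[pos_idx, , drop = FALSE], cfg)
    if (cfg$background_sd > 0) {
      nuclear <- nuclear + matrix(rnorm(length(nuclear), 0,
                                        cfg$background_sd),
                                  nrow(nuclear), ncol(nuclear))
      marker <- marker + matrix(rnorm(length(marker), 0,
                                      cfg$background_sd),
                                nrow(marker), ncol(marker))
    }
    nuclear <- pmin(pmax(nuclear, 0), 1)
    marker <- pmin(pmax(marker, 0), 1)
    img <- two_channel_image(nuclear, marker)
    attr(img, "ground_truth") <-
      tibble(total_nuclei = cfg$n_nuclei, positive_nuclei = n_pos,
             percent_positive = if (cfg$n_nuclei > 0)
               100 * n_pos / cfg$n_nuclei else NA_real_)
    attr(img, "centers") <- centers
    img
  })
}
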