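#' Read particle tracks from a tracking XML export
#'
#' Parses the simplified track XML dialect produced by TrackMate-style
#' exporters. Two layouts are recognised: `<particle>` elements holding
#' `<detection t=".." x=".." y=".."/>` children, and `<Track>` elements
#' holding `<Spot>` children with `FRAME`/`POSITION_X`/`POSITION_Y` (or
#' lower-case `frame`/`x`/`y`) attributes. Positions are multiplied by
#' `unit_scale` (use the pixel size in um/pixel for pixel-unit exports, or 1
#' for exports already in um); times are `frame * frame_interval`. Tracks
#' with fewer than 2 detections are dropped with a warning.
#'
#' @param path Path to the XML file.
#' @param frame_interval Seconds between frames (> 0).
#' @param unit_scale Multiplicative conversion applied to x/y (default 1).
#' @return A trajectory-set tibble with columns `trajectory_id`, `frame`,
#'   `t_s`, `x_um`, `y_um`, ordered by id then frame.
#' @export
read_tracking_xml <- function(path, frame_interval, unit_scale = 1) {
  if (frame_interval <= 0) abort("`frame_interval` must be > 0.")
  doc <- xml2::read_xml(path)
  tracks <- xml2::xml_find_all(doc, ".//particle")
  spot_xp <- "./detection"
  if (length(tracks) == 0) {
    tracks <- xml2::xml_find_all(doc, ".//Track")
    spot_xp <- "./Spot"
  }
  if (length(tracks) == 0) abort("no <particle> or <Track> elements found.")
  get_attr <- function(nodes, names) {
    for (nm in names) {
      v <- xml2::xml_attr(nodes, nm)
      if (!all(is.na(v))) return(as.numeric(v))
    }
    abort(paste0("missing positional attribute (tried: ",
                 paste(names, collapse = ", "), ")."))
  }
  rows <- purrr::imap(tracks, function(trk, i) {
    spots <- xml2::xml_find_all(trk, spot_xp)
    if (length(spots) < 2) return(NULL)
    tibble(trajectory_id = i,
           frame = as.integer(get_attr(spots, c("t", "FRAME", "frame"))),
           x_um = get_attr(spots, c("x", "POSITION_X")) * unit_scale,
           y_um = get_attr(spots, c("y", "POSITION_Y")) * unit_scale)
  })
  n_dropped <- sum(purrr::map_lgl(rows, is.null))
  if (n_dropped > 0)
    warn(paste0("dropped ", n_dropped, " track(s) with fewer than 2 spots."))
  out <- bind_rows(rows)
  if (nrow(out) == 0) abort("no track with >= 2 spots in file.")
  out <- out %>%
    mutate(t_s = .data$frame * frame_interval) %>%
    select("trajectory_id", "frame", "t_s", "x_um", "y_um") %>%
    arrange(.data$trajectory_id, .data$frame)
  structure(out, frame_interval = frame_interval,
            class = c("trajectory_set", class(out)))
}

canonical_cols <- c("trajectory_id", "frame", "t_s", "x_um", "y_um")

#' Read / write trajectories in the canonical CSV layout
#'
#' The canonical layout has columns `trajectory_id`, `frame`, `t_s`, `x_um`,
#' `y_um`. Rows are ordered by id then frame on both read and write, so
#' round-trips are lossless (to full double precision) and input row order
#' is irrelevant. Duplicate `(trajectory_id, frame)` pairs are an error.
#'
#' @param path File path.
#' @param frame_interval Seconds between frames; if `NULL`, inferred from
#'   the median of `diff(t_s) / diff(frame)` within trajectories.
#' @return `read_trajectory_csv()` returns a trajectory-set tibble;
#'   `write_trajectory_csv()` invisibly returns `path`.
#' @export
read_trajectory_csv <- function(path, frame_interval = NULL) {
  out <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  missing <- setdiff(canonical_cols, names(out))
  if (length(missing))
    abort(paste0("missing column(s): ", paste(missing, collapse = ", ")))
  out <- out %>% select(dplyr::all_of(canonical_cols)) %>%
    arrange(.data$trajectory_id, .data$frame)
  if (anyDuplicated(out[c("trajectory_id", "frame")]))
    abort("duplicated (trajectory_id, frame) pairs in file.")
  if (is.null(frame_interval)) {
    if (nrow(out) > 1) {
      d <- out %>% group_by(.data$trajectory_id) %>%
        summarise(dt = list(diff(.data$t_s) / diff(.data$frame)),
                  .groups = "drop")
      dts <- unlist(d$dt)
      frame_interval <- if (length(dts)) median(dts) else NA_real_
    } else frame_interval <- NA_real_
  }
  structure(out, frame_interval = frame_interval,
            class = c("trajectory_set", class(out)))
}

#' @param x A trajectory-set tibble (canonical columns).
#' @rdname read_trajectory_csv
#' @export
write_trajectory_csv <- function(x, path) {
  missing <- setdiff(canonical_cols, names(x))
  if (length(missing))
    abort(paste0("missing column(s): ", paste(missing, collapse = ", ")))
  out <- as_tibble(x)[canonical_cols] %>%
    arrange(.data$trajectory_id, .data$frame)
  readr::write_csv(out, path, progress = FALSE)
  invisible(path)
}

#' Write ground-truth labels as a sidecar CSV
#'
#' @param x A simulated trajectory set carrying ground truth.
#' @param path File path.
#' @export
write_ground_truth_csv <- function(x, path) {
  readr::write_csv(ground_truth(x), path, progress = FALSE)
  invisible(path)
}

#' Apply trajectory-quality filters
#'
#' Removes trajectories shorter than `min_length` frames and handles frame
#' gaps larger than `max_gap`: `"split"` cuts the trajectory at each
#' offending gap into independent segments (segment ids get a `.k` suffix),
#' `"drop"` discards the whole trajectory. Splitting is preferred over
#' interpolation, which would fabricate displacements and bias the MSD
#' downward at short lags. The operation is idempotent. A summary of removed
#' and split counts is attached as attribute `"filter_report"`.
#'
#' @param x A trajectory-set tibble.
#' @param min_length Minimum surviving length in frames (>= 2, inclusive
#'   boundary). Default 10 so that anomalous-exponent fits have at least 9
#'   lags.
#' @param max_gap Largest tolerated frame step: successive points with
#'   `diff(frame) > max_gap` trigger the gap policy. Default 1, i.e. only
#'   consecutive frames are tolerated.
#' @param gap_policy `"split"` (default) or `"drop"`.
#' @return The filtered trajectory-set tibble.
#' @export
filter_trajectories <- function(x, min_length = 10, max_gap = 1,
                                gap_policy = c("split", "drop")) {
  gap_policy <- match.arg(gap_policy)
  if (min_length < 2) abort("`min_length` must be >= 2.")
  n_in <- dplyr::n_distinct(x$trajectory_id)
  pieces <- x %>% arrange(.data$trajectory_id, .data$frame) %>%
    group_by(.data$trajectory_id) %>%
    mutate(.gap = c(0, diff(.data$frame)) > max_gap,
           .seg = cumsum(.data$.gap)) %>%
    ungroup()
  n_split <- 0L
  if (any(pieces$.gap)) {
    if (gap_policy == "drop") {
      gappy <- unique(pieces$trajectory_id[pieces$.gap])
      pieces <- pieces %>% filter(!(.data$trajectory_id %in% gappy))
    } else {
      n_split <- length(unique(pieces$trajectory_id[pieces$.gap]))
      pieces <- pieces %>%
        mutate(trajectory_id = ifelse(
          .data$.seg > 0 | .data$trajectory_id %in%
            unique(.data$trajectory_id[.data$.gap]),
          paste0(.data$trajectory_id, ".", .data$.seg + 1L),
          as.character(.data$trajectory_id)))
    }
  }
  out <- pieces %>% select(-".gap", -".seg") %>%
    group_by(.data$trajectory_id) %>% filter(dplyr::n() >= min_length) %>%
    ungroup() %>% arrange(.data$trajectory_id, .data$frame)
  n_out <- dplyr::n_distinct(out$trajectory_id)
  report <- list(n_in = n_in, n_out = n_out, n_split = n_split)
  structure(out, frame_interval = attr(x, "frame_interval"),
            filter_report = report,
            class = c("trajectory_set", class(as_tibble(out))))
}
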