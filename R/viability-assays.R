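#' Generate a longitudinal plate-reader assay table
#'
#' Emulates alamarBlue / LDH plate exports: for every schedule row
#' (experimental group x timepoint, with a target mean and noise SD),
#' `n_slices` slices each contribute `n_replicates` wells drawn i.i.d.
#' Gaussian around the target mean. Exactly one `TX100_acute` full-lysis
#' control row is required, mirroring the 100% release control. Timepoint
#' ordering follows first appearance in the schedule.
#'
#' @param schedule Data frame with columns `group`, `timepoint`, `mean`,
#'   `sd`, and optionally `n_slices` (default 6).
#' @param n_replicates Wells per slice per timepoint (default 3,
#'   triplicate).
#' @param seed Integer seed for reproducibility.
#' @return An assay tibble: `slice_id`, `group`, `timepoint` (ordered
#'   factor), `replicate`, `reading`, `is_lysis_control`.
#' @export
generate_assay_table <- function(schedule, n_replicates = 3, seed = NULL) {
  schedule <- as_tibble(schedule)
  if (nrow(schedule) == 0) abort("`schedule` is empty.")
  need <- c("group", "timepoint", "mean", "sd")
  missing <- setdiff(need, names(schedule))
  if (length(missing))
    abort(paste0("schedule lacks column(s): ",
                 paste(missing, collapse = ", ")))
  if (sum(schedule$group == "TX100_acute") != 1)
    abort("schedule must contain exactly one TX100_acute control row.")
  if (!"n_slices" %in% names(schedule)) schedule$n_slices <- 6L
  tp_levels <- unique(as.character(schedule$timepoint))
  run_seeded(seed, {
    rows <- purrr::pmap(schedule, function(group, timepoint, mean, sd,
                                           n_slices, ...) {
      k <- n_slices * n_replicates
      tibble(slice_id = paste0(group, "_s",
                               rep(seq_len(n_slices), each = n_replicates)),
             group = group, timepoint = as.character(timepoint),
             replicate = rep(seq_len(n_replicates), n_slices),
             reading = mean + rnorm(k, 0, sd))
    })
    out <- bind_rows(rows) %>%
      mutate(timepoint = factor(.data$timepoint, levels = tp_levels),
             is_lysis_control = startsWith(.data$group, "TX100"))
    out
  })
}

#' Average replicate wells
#'
#' One arithmetic-mean row per (slice, group, timepoint), the standard
#' "run in triplicate, report the average" reduction.
#'
#' @param table An assay tibble with `slice_id`, `group`, `timepoint`,
#'   `reading` (and optionally `replicate`, `is_lysis_control`).
#' @return The reduced tibble with a `n_replicates` column.
#' @export
average_replicates <- function(table) {
  if (nrow(table) == 0) abort("`table` is empty.")
  keys <- intersect(c("slice_id", "group", "timepoint", "is_lysis_control"),
                    names(table))
  table %>% group_by(across(dplyr::all_of(keys))) %>%
    summarise(reading = mean(.data$reading), n_replicates = dplyr::n(),
              .groups = "drop")
}

#' Normalize metabolic-activity readings
#'
#' Two normalization bases are supported. `"acute_mean"` expresses every
#' reading as a percentage of the mean reading at the acute timepoint of
#' the same group (the acute mean is set at 100%), the reduction used for
#' normal-control time courses. `"NC_mean"` expresses each reading as a
#' percentage of the mean reading of the normal-control group at the same
#' timepoint and additionally reports the percentage difference from NC
#' (`value - 100`), the reduction used for treated-vs-control studies.
#'
#' @param table An assay tibble (replicates are averaged internally; the
#'   operation commutes with [average_replicates()]).
#' @param basis `"acute_mean"` or `"NC_mean"`.
#' @param acute_label Timepoint label of the acute baseline (default
#'   `"acute"`).
#' @param nc_group Group label of the normal control (default `"NC"`).
#' @return A tibble with `slice_id`, `group`, `timepoint`, `value`
#'   (percent), `basis`, and for the NC basis `pct_diff_from_nc`.
#' @export
normalize_metabolic <- function(table, basis = c("acute_mean", "NC_mean"),
                                acute_label = "acute", nc_group = "NC") {
  basis <- match.arg(basis)
  avg <- average_replicates(table)
  if (basis == "acute_mean") {
    base <- avg %>% filter(as.character(.data$timepoint) == acute_label) %>%
      group_by(.data$group) %>%
      summarise(base_mean = mean(.data$reading), .groups = "drop")
    if (nrow(base) == 0) abort("no rows at the acute timepoint.")
    out <- avg %>% left_join(base, by = "group")
    if (any(is.na(out$base_mean)))
      abort("some groups lack an acute baseline.")
  } else {
    base <- avg %>% filter(.data$group == nc_group) %>%
      group_by(.data$timepoint) %>%
      summarise(base_mean = mean(.data$reading), .groups = "drop")
    if (nrow(base) == 0) abort("no normal-control rows found.")
    out <- avg %>% left_join(base, by = "timepoint")
    if (any(is.na(out$base_mean)))
      abort("some timepoints lack a normal-control baseline.")
  }
  if (any(out$base_mean == 0)) abort("zero basis mean; cannot normalize.")
  out <- out %>%
    mutate(value = 100 * .data$reading / .data$base_mean, basis = basis) %>%
    select(dplyr::any_of(c("slice_id", "group", "timepoint", "value",
                           "basis")))
  if (basis == "NC_mean") out$pct_diff_from_nc <- out$value - 100
  out
}

#' Cumulative percent LDH release
#'
#' Culture media are exchanged at every collection, so each reading is the
#' LDH released during that interval; the cumulative release of a slice up
#' to a timepoint is the running sum of its per-interval readings. The
#' percentage is taken against the mean absorbance of the acute TX-100
#' full-lysis control: `%LDH = 100 * cumulative sample absorbance /
#' TX-100 acute absorbance`. The series is nondecreasing by construction
#' and may exceed 100% (total release can pass the single-lysis control),
#' so no cap is applied.
#'
#' @param table An assay tibble; must contain rows with
#'   `group == control_group`.
#' @param control_group Label of the full-lysis acute control (default
#'   `"TX100_acute"`); its rows are pooled into a single denominator and
#'   excluded from the output series.
#' @return A tibble with `slice_id`, `group`, `timepoint`, `value`
#'   (cumulative percent), `basis`.
#' @export
cumulative_ldh_release <- function(table, control_group = "TX100_acute") {
  avg <- average_replicates(table)
  ctrl <- avg %>% filter(.data$group == control_group)
  if (nrow(ctrl) == 0)
    abort(paste0("control group '", control_group, "' not found."))
  denom <- mean(ctrl$reading)
  if (denom == 0) abort("zero control absorbance; cannot normalize.")
  series <- avg %>% filter(.data$group != control_group)
  if (!is.factor(series$timepoint)) {
    warn("`timepoint` is not a factor; using order of appearance.")
    series$timepoint <- factor(series$timepoint,
                               levels = unique(series$timepoint))
  }
  series %>%
    arrange(.data$slice_id, .data$timepoint) %>%
    group_by(.data$slice_id, .data$group) %>%
    mutate(value = 100 * cumsum(.data$reading) / denom) %>%
    ungroup() %>%
    mutate(basis = control_group) %>%
    select("slice_id", "group", "timepoint", "value", "basis")
}

#' Plot normalized assay time courses
#'
#' @param series A normalized tibble from [normalize_metabolic()] or
#'   [cumulative_ldh_release()].
#' @return A ggplot object (one line per slice, coloured by group).
#' @export
plot_assay_series <- function(series) {
  ggplot2::ggplot(series,
                  ggplot2::aes(x = .data$timepoint, y = .data$value,
                               group = .data$slice_id,
                               colour = .data$group)) +
    ggplot2::geom_line(alpha = 0.6) + ggplot2::geom_point(size = 1) +
    ggplot2::labs(x = "timepoint", y = "% of basis") +
    ggplot2::theme_minimal()
}
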