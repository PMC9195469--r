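#' Time-averaged mean squared displacement of one trajectory
#'
#' For a trajectory of `N` points on a uniform frame grid, the MSD at lag
#' `n` frames is the average over all `N - n` start points of the squared
#' two-dimensional displacement:
#' `msd(n) = (1/(N-n)) * sum_i [ (x_{i+n}-x_i)^2 + (y_{i+n}-y_i)^2 ]`.
#'
#' @param traj A single trajectory: data frame with `frame`, `x_um`, `y_um`
#'   (and optionally `trajectory_id`, `t_s`).
#' @param max_lag Largest lag in frames. Default `floor(N/3)`, a common
#'   single-particle-tracking convention that avoids the high-variance long
#'   lags.
#' @param frame_interval Seconds between frames, used to convert lags to
#'   `tau`; taken from the set attribute when present.
#' @return A tibble with columns `trajectory_id`, `lag`, `tau`, `msd`,
#'   `n_pairs` (`n_pairs = N - lag`).
#' @export
compute_msd <- function(traj, max_lag = NULL, frame_interval = NULL) {
  if (is.null(frame_interval)) frame_interval <- attr(traj, "frame_interval")
  if (is.null(frame_interval) && "t_s" %in% names(traj) && nrow(traj) > 1)
    frame_interval <- (traj$t_s[2] - traj$t_s[1]) /
      (traj$frame[2] - traj$frame[1])
  if (is.null(frame_interval) || !is.finite(frame_interval) ||
      frame_interval <= 0)
    abort("a positive `frame_interval` is required.")
  if ("trajectory_id" %in% names(traj) &&
      dplyr::n_distinct(traj$trajectory_id) > 1)
    abort("`traj` must contain a single trajectory; see `msd_profiles()`.")
  o <- order(traj$frame)
  fr <- traj$frame[o]; x <- traj$x_um[o]; y <- traj$y_um[o]
  N <- length(x)
  if (N < 2) abort("trajectory must have at least 2 points.")
  if (any(diff(fr) != diff(fr)[1]) || diff(fr)[1] != 1)
    abort("trajectory is not on a uniform consecutive frame grid; filter or split first.")
  if (is.null(max_lag)) max_lag <- max(1L, floor(N / 3))
  max_lag <- as.integer(max_lag)
  if (max_lag < 1 || max_lag > N - 1)
    abort("`max_lag` must lie in [1, N - 1].")
  msd <- vapply(seq_len(max_lag), function(n) {
    dx <- x[(1 + n):N] - x[1:(N - n)]
    dy <- y[(1 + n):N] - y[1:(N - n)]
    mean(dx * dx + dy * dy)
  }, numeric(1))
  id <- if ("trajectory_id" %in% names(traj)) traj$trajectory_id[1] else NA
  tibble(trajectory_id = id, lag = seq_len(max_lag),
         tau = seq_len(max_lag) * frame_interval, msd = msd,
         n_pairs = N - seq_len(max_lag))
}

#' Per-trajectory MSD profiles for a whole trajectory set
#'
#' @param x A trajectory-set tibble.
#' @param max_lag Largest lag in frames; `NULL` (default) uses
#'   `floor(N/3)` per trajectory.
#' @inheritParams compute_msd
#' @return A long tibble of MSD profiles (one row per trajectory and lag).
#' @export
msd_profiles <- function(x, max_lag = NULL, frame_interval = NULL) {
  if (is.null(frame_interval)) frame_interval <- attr(x, "frame_interval")
  x %>% group_by(.data$trajectory_id) %>% group_split() %>%
    purrr::map(compute_msd, max_lag = max_lag,
               frame_interval = frame_interval) %>%
    bind_rows()
}

#' Precision-weighted geometric ensemble MSD
#'
#' At each lag the ensemble value is the weighted geometric mean of the
#' per-trajectory MSDs, `exp( sum(w_i log msd_i) / sum(w_i) )`, over
#' trajectories with `msd > 0` and at least one displacement pair. Weights:
#' `"pairs"` (default) uses the number of displacement pairs `N - n` as the
#' precision proxy, `"inverse_variance"` uses `n_pairs / msd^2`
#' (the delta-method inverse variance of the MSD estimate), `"none"` uses
#' equal weights. Lags at which every trajectory has `msd == 0` report 0.
#'
#' @param profiles A long MSD-profile tibble from [msd_profiles()].
#' @param weighting `"pairs"`, `"inverse_variance"` or `"none"`.
#' @return A tibble with `lag`, `tau`, `geo_msd`, `weight_sum`,
#'   `n_trajectories`.
#' @export
ensemble_msd <- function(profiles,
                         weighting = c("pairs", "inverse_variance", "none")) {
  weighting <- match.arg(weighting)
  if (nrow(profiles) == 0) abort("`profiles` is empty.")
  profiles %>% group_by(.data$lag, .data$tau) %>%
    summarise(geo_msd = {
      ok <- .data$msd > 0 & .data$n_pairs >= 1
      if (!any(ok)) 0 else {
        w <- switch(weighting,
                    pairs = .data$n_pairs[ok],
                    inverse_variance = .data$n_pairs[ok] / .data$msd[ok]^2,
                    none = rep(1, sum(ok)))
        exp(sum(w * log(.data$msd[ok])) / sum(w))
      }
    },
    weight_sum = {
      ok <- .data$msd > 0 & .data$n_pairs >= 1
      switch(weighting,
             pairs = sum(.data$n_pairs[ok]),
             inverse_variance = sum(.data$n_pairs[ok] / .data$msd[ok]^2),
             none = sum(ok))
    },
    n_trajectories = sum(.data$msd > 0 & .data$n_pairs >= 1),
    .groups = "drop") %>%
    arrange(.data$lag)
}

resolve_lags <- function(profile, lags) {
  got <- intersect(lags, profile$lag)
  if (length(got) == 0) abort("no requested lag is available in the profile.")
  got
}

#' Effective diffusion coefficient from the Einstein-Smoluchowski relation
#'
#' For two-dimensional diffusion, `D_eff = MSD / (4 tau)`. With a window of
#' lags (the default, lags 1..10, about 0.03-0.30 s at 33.3 fps) the mean of
#' `msd/(4 tau)` over the window is returned.
#'
#' @param profile A single-trajectory MSD tibble from [compute_msd()].
#' @param lags Lag window (frames); a single lag gives the single-lag value.
#' @return `D_eff` in um^2/s (non-negative scalar).
#' @export
compute_deff <- function(profile, lags = 1:10) {
  use <- resolve_lags(profile, lags)
  p <- profile[profile$lag %in% use, ]
  mean(p$msd / (4 * p$tau))
}

#' Fit the anomalous diffusion exponent
#'
#' Fits `MSD = 4 D tau^alpha` by ordinary least squares of `log(msd)` on
#' `log(tau)` over the fit window (default lags 1..min(30, max available)).
#' Zero-MSD lags are excluded from the log fit; a trajectory with fewer than
#' 3 positive-MSD lags in the window is a perfectly (or almost perfectly)
#' immobile particle and is assigned `alpha = 0` with `degenerate = TRUE`
#' rather than an error.
#'
#' @param profile A single-trajectory MSD tibble from [compute_msd()].
#' @param lags Fit window in frames; `NULL` uses `1:min(30, max_lag)`.
#' @return A one-row tibble: `alpha`, `D_fit` (um^2/s), `fit_r2`,
#'   `n_lags_fit`, `degenerate`.
#' @export
fit_alpha <- function(profile, lags = NULL) {
  if (is.null(lags)) lags <- seq_len(min(30L, max(profile$lag)))
  use <- resolve_lags(profile, lags)
  p <- profile[profile$lag %in% use & profile$msd > 0, ]
  if (nrow(p) < 3) {
    return(tibble(alpha = 0, D_fit = 0, fit_r2 = NA_real_,
                  n_lags_fit = nrow(p), degenerate = TRUE))
  }
  fit <- lm(log(msd) ~ log(tau), data = p)
  ss_res <- sum(fit$residuals^2)
  ss_tot <- sum((log(p$msd) - mean(log(p$msd)))^2)
  r2 <- if (ss_tot == 0) 1 else 1 - ss_res / ss_tot
  tibble(alpha = unname(coef(fit)[2]),
         D_fit = exp(unname(coef(fit)[1])) / 4,
         fit_r2 = r2,
         n_lags_fit = nrow(p), degenerate = FALSE)
}

#' Classify diffusion mode from the anomalous exponent
#'
#' Maps `alpha` to one of four motion classes: immobile (`alpha < 0.1`),
#' subdiffusive (`0.1 <= alpha < 0.9`), normal (`0.9 <= alpha <= 1.1`),
#' superdiffusive (`1.1 < alpha`). The boundary values 0.1, 0.9 and 1.1 are
#' assigned to subdiffusive, normal and normal respectively.
#'
#' @param alpha Numeric vector of finite anomalous exponents.
#' @return A factor with levels `immobile`, `subdiffusive`, `normal`,
#'   `superdiffusive`.
#' @export
classify_mode <- function(alpha) {
  if (any(!is.finite(alpha)))
    abort("`alpha` must be finite (no NA/NaN/Inf).")
  lv <- c("immobile", "subdiffusive", "normal", "superdiffusive")
  out <- ifelse(alpha < 0.1, "immobile",
                ifelse(alpha < 0.9, "subdiffusive",
                       ifelse(alpha <= 1.1, "normal", "superdiffusive")))
  factor(out, levels = lv)
}

#' Per-trajectory diffusion summaries for a trajectory set
#'
#' Runs the full per-trajectory chain: MSD profile, windowed `D_eff`,
#' log-log `alpha` fit, and mode classification.
#'
#' @param x A trajectory-set tibble.
#' @param deff_lags Lag window for `D_eff` (default 1:10).
#' @param alpha_lags Fit window for `alpha`; `NULL` = `1:min(30, max_lag)`.
#' @param max_lag Largest computed lag; `NULL` = `floor(N/3)`.
#' @inheritParams compute_msd
#' @return A tibble with one row per trajectory: `trajectory_id`, `D_eff`,
#'   `alpha`, `fit_r2`, `degenerate`, `mode`.
#' @export
fit_diffusion <- function(x, deff_lags = 1:10, alpha_lags = NULL,
                          max_lag = NULL, frame_interval = NULL) {
  if (is.null(frame_interval)) frame_interval <- attr(x, "frame_interval")
  x %>% group_by(.data$trajectory_id) %>% group_split() %>%
    purrr::map(function(tr) {
      prof <- compute_msd(tr, max_lag = max_lag,
                          frame_interval = frame_interval)
      af <- fit_alpha(prof, lags = alpha_lags)
      tibble(trajectory_id = tr$trajectory_id[1],
             D_eff = compute_deff(prof, lags = deff_lags),
             alpha = af$alpha, fit_r2 = af$fit_r2,
             degenerate = af$degenerate)
    }) %>%
    bind_rows() %>%
    mutate(mode = classify_mode(.data$alpha))
}

#' Population summary of per-trajectory diffusion results
#'
#' Median and interquartile range of `D_eff`, median `alpha`, and the
#' fractions of trajectories in each of the four diffusion modes (which sum
#' to 1).
#'
#' @param summaries A per-trajectory summary tibble from [fit_diffusion()].
#' @return A one-row tibble.
#' @export
summarize_population <- function(summaries) {
  if (nrow(summaries) == 0) abort("`summaries` is empty.")
  lv <- c("immobile", "subdiffusive", "normal", "superdiffusive")
  fr <- as.numeric(table(factor(summaries$mode, levels = lv))) /
    nrow(summaries)
  tibble(n_trajectories = nrow(summaries),
         D_eff_median = median(summaries$D_eff),
         D_eff_q25 = unname(quantile(summaries$D_eff, 0.25)),
         D_eff_q75 = unname(quantile(summaries$D_eff, 0.75)),
         alpha_median = median(summaries$alpha),
         frac_immobile = fr[1], frac_subdiffusive = fr[2],
         frac_normal = fr[3], frac_superdiffusive = fr[4])
}

#' End-to-end diffusion analysis of a trajectory set
#'
#' Convenience driver producing the per-trajectory summaries, the
#' precision-weighted geometric ensemble MSD and the population summary in
#' one object, with the settings used echoed for reproducibility.
#'
#' @inheritParams fit_diffusion
#' @param weighting Ensemble weighting scheme, see [ensemble_msd()].
#' @return An object of class `mpt_analysis` with components
#'   `per_trajectory`, `ensemble`, `population`, `settings`. [tidy()] returns
#'   the per-trajectory table, [glance()] the one-row population summary,
#'   [autoplot()] a log-log ensemble MSD plot.
#' @export
analyze_diffusion <- function(x, deff_lags = 1:10, alpha_lags = NULL,
                              max_lag = NULL, frame_interval = NULL,
                              weighting = "pairs") {
  if (is.null(frame_interval)) frame_interval <- attr(x, "frame_interval")
  per <- fit_diffusion(x, deff_lags = deff_lags, alpha_lags = alpha_lags,
                       max_lag = max_lag, frame_interval = frame_interval)
  prof <- msd_profiles(x, max_lag = max_lag, frame_interval = frame_interval)
  ens <- ensemble_msd(prof, weighting = weighting)
  structure(list(per_trajectory = per, ensemble = ens,
                 population = summarize_population(per),
                 settings = list(deff_lags = deff_lags,
                                 alpha_lags = alpha_lags %||% "1:min(30,max_lag)",
                                 max_lag = max_lag %||% "floor(N/3)",
                                 frame_interval = frame_interval,
                                 weighting = weighting)),
            class = "mpt_analysis")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @method tidy mpt_analysis
#' @export
tidy.mpt_analysis <- function(x, ...) x$per_trajectory

#' @method glance mpt_analysis
#' @export
glance.mpt_analysis <- function(x, ...) x$population

#' @export
print.mpt_analysis <- function(x, ...) {
  cat("<mpt_analysis> ", x$population$n_trajectories, " trajectories\n", sep = "")
  cat(sprintf("  median D_eff: %.4g um^2/s  (IQR %.4g-%.4g)\n",
              x$population$D_eff_median, x$population$D_eff_q25,
              x$population$D_eff_q75))
  cat(sprintf("  median alpha: %.3f\n", x$population$alpha_median))
  cat(sprintf("  modes: %.1f%% immobile, %.1f%% subdiffusive, %.1f%% normal, %.1f%% superdiffusive\n",
              100 * x$population$frac_immobile,
              100 * x$population$frac_subdiffusive,
              100 * x$population$frac_normal,
              100 * x$population$frac_superdiffusive))
  invisible(x)
}

#' @method autoplot mpt_analysis
#' @export
autoplot.mpt_analysis <- function(object, ...) {
  ens <- object$ensemble %>% filter(.data$geo_msd > 0)
  ggplot2::ggplot(ens, ggplot2::aes(x = .data$tau, y = .data$geo_msd)) +
    ggplot2::geom_line() + ggplot2::geom_point(size = 1) +
    ggplot2::scale_x_log10() + ggplot2::scale_y_log10() +
    ggplot2::labs(x = expression(tau ~ "(s)"),
                  y = expression("<MSD> (" * mu * m^2 * ")"),
                  title = "Precision-weighted geometric ensemble MSD") +
    ggplot2::theme_minimal()
}

#' Distribution plot of per-trajectory effective diffusion coefficients
#'
#' @param summaries A per-trajectory tibble from [fit_diffusion()].
#' @return A ggplot object.
#' @export
plot_deff_distribution <- function(summaries) {
  ggplot2::ggplot(summaries, ggplot2::aes(x = .data$D_eff)) +
    ggplot2::geom_histogram(bins = 40) +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = expression(D[eff] ~ "(" * mu * m^2 * "/s)"),
                  y = "trajectories") +
    ggplot2::theme_minimal()
}
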