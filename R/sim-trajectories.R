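#' Simulation configuration for synthetic particle trajectories
#'
#' Bundles the acquisition geometry and motion model used by the trajectory
#' generators. Defaults mirror the MPT acquisition the pipeline targets:
#' videos at 33.3 frames per second for 651 frames, trajectories in physical
#' micrometres. Localization noise is i.i.d. Gaussian per frame and axis,
#' the standard single-particle-tracking noise model.
#'
#' @param n_trajectories Number of trajectories to generate.
#' @param n_frames Frames per trajectory (>= 2). Default 651.
#' @param frame_interval Seconds between frames. Default `1 / 33.3`.
#' @param localization_noise_sd Static localization error, micrometres
#'   (standard deviation per axis per frame). Default 0.02.
#' @param pixel_size Micrometres per pixel, used only when pixel-unit output
#'   is requested downstream. Default 0.1.
#' @param regime Motion model: `"brownian"`, `"fbm"`, `"immobile"`,
#'   `"directed"` or `"mixture"`.
#' @param D Diffusion coefficient, um^2/s (Brownian and directed regimes;
#'   generalized coefficient for fBm so that MSD = 4 D tau^(2H)).
#' @param hurst Hurst exponent in (0, 1) for the fBm regime.
#' @param velocity Drift speed, um/s, for the directed regime.
#' @param mixture Named numeric vector of regime fractions (non-negative,
#'   summing to 1 within 1e-9) for the mixture regime, e.g.
#'   `c(brownian = 0.5, immobile = 0.5)`.
#' @param seed Integer seed; identical config + seed reproduces trajectories
#'   bitwise.
#' @return A `sim_config` list, validated.
#' @export
sim_config <- function(n_trajectories = 100, n_frames = 651,
                       frame_interval = 1 / 33.3,
                       localization_noise_sd = 0.02, pixel_size = 0.1,
                       regime = c("brownian", "fbm", "immobile", "directed",
                                  "mixture"),
                       D = 0.5, hurst = 0.5, velocity = 0.5,
                       mixture = NULL, seed = NULL) {
  regime <- match.arg(regime)
  if (n_trajectories < 1) abort("`n_trajectories` must be >= 1.")
  if (n_frames < 2) abort("`n_frames` must be >= 2.")
  if (frame_interval <= 0) abort("`frame_interval` must be > 0.")
  if (localization_noise_sd < 0) abort("`localization_noise_sd` must be >= 0.")
  if (regime %in% c("brownian", "fbm") && D <= 0)
    abort("`D` must be > 0 for this regime.")
  if (regime == "fbm" && (hurst <= 0 || hurst >= 1))
    abort("`hurst` must lie strictly inside (0, 1).")
  if (regime == "directed" && velocity <= 0)
    abort("`velocity` must be > 0 for the directed regime.")
  if (regime == "mixture") {
    if (is.null(mixture) || is.null(names(mixture)))
      abort("`mixture` must be a named vector of regime fractions.")
    if (any(mixture < 0)) abort("mixture fractions must be non-negative.")
    if (abs(sum(mixture) - 1) > 1e-9)
      abort("mixture fractions must sum to 1 (within 1e-9).")
    bad <- setdiff(names(mixture), c("brownian", "fbm", "immobile", "directed"))
    if (length(bad)) abort(paste0("unknown mixture regime: ", bad[1]))
  }
  structure(list(n_trajectories = as.integer(n_trajectories),
                 n_frames = as.integer(n_frames),
                 frame_interval = frame_interval,
                 localization_noise_sd = localization_noise_sd,
                 pixel_size = pixel_size, regime = regime, D = D,
                 hurst = hurst, velocity = velocity, mixture = mixture,
                 seed = seed),
            class = "sim_config")
}

# assemble a trajectory-set tibble from per-trajectory x/y matrices
# (n_frames x n_trajectories), attaching ground truth
new_trajectory_set <- function(x, y, cfg, truth, id_offset = 0L) {
  n <- cfg$n_frames
  k <- ncol(x)
  ids <- rep(seq_len(k) + id_offset, each = n)
  out <- tibble(
    trajectory_id = ids,
    frame = rep(0:(n - 1L), k),
    t_s = rep((0:(n - 1L)) * cfg$frame_interval, k),
    x_um = as.vector(x),
    y_um = as.vector(y)
  )
  truth <- tibble(trajectory_id = seq_len(k) + id_offset,
                  regime = truth$regime, true_D = truth$true_D,
                  true_alpha = truth$true_alpha)
  structure(out, ground_truth = truth, frame_interval = cfg$frame_interval,
            class = c("trajectory_set", class(out)))
}

add_noise <- function(m, sd) {
  if (sd <= 0) return(m)
  m + matrix(rnorm(length(m), 0, sd), nrow(m), ncol(m))
}

sim_brownian_core <- function(cfg, k = cfg$n_trajectories) {
  n <- cfg$n_frames
  step_sd <- sqrt(2 * cfg$D * cfg$frame_interval)
  x <- apply(matrix(rnorm((n - 1) * k, 0, step_sd), n - 1, k), 2, cumsum)
  y <- apply(matrix(rnorm((n - 1) * k, 0, step_sd), n - 1, k), 2, cumsum)
  list(x = rbind(0, matrix(x, n - 1, k)), y = rbind(0, matrix(y, n - 1, k)))
}

#' Simulate freely diffusing (Brownian) trajectories
#'
#' Per-axis increments are independent Gaussian with variance
#' `2 * D * frame_interval`; i.i.d. localization noise is added afterwards,
#' so the ensemble MSD is `4 D tau + 4 sigma^2`.
#'
#' @param cfg A [sim_config()] with `regime = "brownian"`.
#' @return A trajectory-set tibble (columns `trajectory_id`, `frame`, `t_s`,
#'   `x_um`, `y_um`) with ground-truth labels retrievable via
#'   [ground_truth()].
#' @export
simulate_brownian <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  if (cfg$regime != "brownian") abort("config regime must be 'brownian'.")
  run_seeded(cfg$seed, {
    p <- sim_brownian_core(cfg)
    truth <- list(regime = "brownian", true_D = cfg$D, true_alpha = 1)
    new_trajectory_set(add_noise(p$x, cfg$localization_noise_sd),
                       add_noise(p$y, cfg$localization_noise_sd), cfg, truth)
  })
}

# lower Cholesky factor of the fractional-Gaussian-noise correlation matrix
fgn_chol <- function(m, hurst) {
  k <- 0:(m - 1)
  rho <- 0.5 * (abs(k + 1)^(2 * hurst) - 2 * abs(k)^(2 * hurst) +
                  abs(k - 1)^(2 * hurst))
  t(chol(stats::toeplitz(rho)))
}

sim_fbm_core <- function(cfg, k = cfg$n_trajectories) {
  n <- cfg$n_frames
  L <- fgn_chol(n - 1, cfg$hurst)
  scale <- sqrt(2 * cfg$D) * cfg$frame_interval^cfg$hurst
  dx <- scale * (L %*% matrix(rnorm((n - 1) * k), n - 1, k))
  dy <- scale * (L %*% matrix(rnorm((n - 1) * k), n - 1, k))
  list(x = rbind(0, apply(dx, 2, cumsum)), y = rbind(0, apply(dy, 2, cumsum)))
}

#' Simulate fractional Brownian motion trajectories
#'
#' Each axis is exact fractional Brownian motion with Hurst exponent `H`,
#' generated by Cholesky factorization of the fractional-Gaussian-noise
#' covariance, so the ensemble MSD scales as `4 D tau^(2H)` and the true
#' anomalous exponent is `alpha = 2H`. `H = 0.5` reduces to Brownian motion;
#' `H < 0.5` gives subdiffusive ground truth.
#'
#' @param cfg A [sim_config()] with `regime = "fbm"` and `hurst` in (0, 1).
#' @inherit simulate_brownian return
#' @export
simulate_fbm <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  if (cfg$regime != "fbm") abort("config regime must be 'fbm'.")
  run_seeded(cfg$seed, {
    p <- sim_fbm_core(cfg)
    truth <- list(regime = "fbm", true_D = cfg$D, true_alpha = 2 * cfg$hurst)
    new_trajectory_set(add_noise(p$x, cfg$localization_noise_sd),
                       add_noise(p$y, cfg$localization_noise_sd), cfg, truth)
  })
}

#' Simulate immobile (stuck) particles
#'
#' True positions are constant; observed positions are the constant plus
#' per-frame localization noise. Expected MSD plateaus at
#' `4 * localization_noise_sd^2` for every lag >= 1 (both endpoints of a
#' displacement carry independent noise on two axes).
#'
#' @param cfg A [sim_config()] with `regime = "immobile"`.
#' @inherit simulate_brownian return
#' @export
simulate_immobile <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  if (cfg$regime != "immobile") abort("config regime must be 'immobile'.")
  run_seeded(cfg$seed, {
    z <- matrix(0, cfg$n_frames, cfg$n_trajectories)
    truth <- list(regime = "immobile", true_D = 0, true_alpha = 0)
    new_trajectory_set(add_noise(z, cfg$localization_noise_sd),
                       add_noise(z, cfg$localization_noise_sd), cfg, truth)
  })
}

#' Simulate directed (flow-like) trajectories
#'
#' Each trajectory drifts at speed `velocity` along a random unit direction,
#' superposed on Brownian motion with coefficient `D` (set `D` near 0 for
#' nearly ballistic motion) plus localization noise. At long lags
#' `MSD -> velocity^2 tau^2`, i.e. `alpha -> 2`.
#'
#' @param cfg A [sim_config()] with `regime = "directed"`; uses `velocity`
#'   and `D` (Brownian component, may be 0).
#' @inherit simulate_brownian return
#' @export
simulate_directed <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  if (cfg$regime != "directed") abort("config regime must be 'directed'.")
  run_seeded(cfg$seed, {
    n <- cfg$n_frames; k <- cfg$n_trajectories
    theta <- runif(k, 0, 2 * pi)
    tt <- (0:(n - 1)) * cfg$frame_interval
    drift_x <- outer(tt, cfg$velocity * cos(theta))
    drift_y <- outer(tt, cfg$velocity * sin(theta))
    if (cfg$D > 0) {
      bcfg <- cfg; bcfg$regime <- "brownian"
      p <- sim_brownian_core(bcfg)
      drift_x <- drift_x + p$x; drift_y <- drift_y + p$y
    }
    truth <- list(regime = "directed", true_D = cfg$D, true_alpha = 2)
    out <- new_trajectory_set(add_noise(drift_x, cfg$localization_noise_sd),
                              add_noise(drift_y, cfg$localization_noise_sd),
                              cfg, truth)
    attr(out, "directions") <- cbind(cos(theta), sin(theta))
    out
  })
}

#' Simulate a mixture of motion regimes
#'
#' Trajectory counts per regime follow the mixture fractions exactly
#' (largest-remainder apportionment), so a 50/50 mixture of 200 trajectories
#' contains exactly 100 of each. Per-regime parameters are taken from the
#' shared config.
#'
#' @param cfg A [sim_config()] with `regime = "mixture"` and a named
#'   `mixture` fraction vector.
#' @inherit simulate_brownian return
#' @export
simulate_mixture <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  if (cfg$regime != "mixture") abort("config regime must be 'mixture'.")
  fr <- cfg$mixture[cfg$mixture > 0]
  raw <- fr * cfg$n_trajectories
  counts <- floor(raw)
  rem <- cfg$n_trajectories - sum(counts)
  if (rem > 0) {
    extra <- order(raw - counts, decreasing = TRUE)[seq_len(rem)]
    counts[extra] <- counts[extra] + 1
  }
  run_seeded(cfg$seed, {
    parts <- list(); offset <- 0L
    for (i in seq_along(counts)) {
      if (counts[i] == 0) next
      sub <- cfg; sub$regime <- names(fr)[i]
      sub$n_trajectories <- as.integer(counts[i]); sub$seed <- NULL
      gen <- switch(names(fr)[i], brownian = simulate_brownian,
                    fbm = simulate_fbm, immobile = simulate_immobile,
                    directed = simulate_directed)
      piece <- gen(sub)
      gt <- ground_truth(piece)
      gt$trajectory_id <- gt$trajectory_id + offset
      piece$trajectory_id <- piece$trajectory_id + offset
      attr(piece, "ground_truth") <- gt
      offset <- offset + counts[i]
      parts[[length(parts) + 1L]] <- piece
    }
    truth <- bind_rows(lapply(parts, ground_truth))
    out <- bind_rows(lapply(parts, function(p) as_tibble(p)))
    structure(out, ground_truth = truth, frame_interval = cfg$frame_interval,
              class = c("trajectory_set", class(out)))
  })
}

#' Simulate trajectories for any configured regime
#'
#' Dispatches on `cfg$regime` to the matching generator.
#'
#' @param cfg A [sim_config()].
#' @inherit simulate_brownian return
#' @export
simulate_trajectories <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  switch(cfg$regime,
         brownian = simulate_brownian(cfg),
         fbm = simulate_fbm(cfg),
         immobile = simulate_immobile(cfg),
         directed = simulate_directed(cfg),
         mixture = simulate_mixture(cfg))
}

# evaluate expr under a local RNG scope when a seed is given
run_seeded <- function(seed, expr) {
  if (is.null(seed)) return(force(expr))
  withr::with_seed(seed, force(expr))
}
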