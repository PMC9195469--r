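# Independent brute-force oracles and small fixture builders.

# naive double-loop time-averaged MSD (the definition, written the slow way:
# every squared displacement computed one pair at a time, then averaged)
msd_oracle <- function(x, y, max_lag, frame_interval) {
  N <- length(x)
  msd <- numeric(max_lag)
  for (n in seq_len(max_lag)) {
    sq <- numeric(N - n)
    for (i in 1:(N - n)) {
      sq[i] <- (x[i + n] - x[i])^2 + (y[i + n] - y[i])^2
    }
    msd[n] <- mean(sq)
  }
  tibble::tibble(lag = seq_len(max_lag), tau = seq_len(max_lag) * frame_interval,
                 msd = msd, n_pairs = N - seq_len(max_lag))
}

# exhaustive-search Otsu: build the same 256-bin histogram, then try every
# candidate bin edge, recomputing class weights and means from scratch
otsu_oracle <- function(v, levels = 256) {
  rng <- range(v)
  breaks <- seq(rng[1], rng[2], length.out = levels + 1)
  bin <- pmin(pmax(findInterval(v, breaks, rightmost.closed = TRUE), 1),
              levels)
  counts <- tabulate(bin, nbins = levels)
  p <- counts / length(v)
  mids <- (breaks[-1] + breaks[-(levels + 1)]) / 2
  best <- -Inf; best_th <- NA_real_
  for (k in 1:(levels - 1)) {
    w0 <- 0; s0 <- 0; w1 <- 0; s1 <- 0
    for (j in 1:k) { w0 <- w0 + p[j]; s0 <- s0 + p[j] * mids[j] }
    for (j in (k + 1):levels) { w1 <- w1 + p[j]; s1 <- s1 + p[j] * mids[j] }
    if (w0 == 0 || w1 == 0) next
    sb2 <- w0 * w1 * (s0 / w0 - s1 / w1)^2
    if (sb2 > best) { best <- sb2; best_th <- breaks[k + 1] }
  }
  best_th
}

# one synthetic random-walk trajectory as a plain tibble
random_traj <- function(n, id = 1L, dt = 0.03003, sd = 0.1) {
  tibble::tibble(trajectory_id = id, frame = 0:(n - 1),
                 t_s = (0:(n - 1)) * dt,
                 x_um = cumsum(c(0, rnorm(n - 1, 0, sd))),
                 y_um = cumsum(c(0, rnorm(n - 1, 0, sd))))
}

# write a minimal TrackMate-style simplified track XML
write_tracks_xml <- function(path, tracks, frame_interval = 0.03003) {
  lines <- c("<?xml version=\"1.0\" encoding=\"UTF-8\"?>",
             sprintf("<Tracks nTracks=\"%d\" frameInterval=\"%g\" spaceUnits=\"pixel\" timeUnits=\"s\">",
                     length(tracks), frame_interval))
  for (trk in tracks) {
    lines <- c(lines, sprintf("  <particle nSpots=\"%d\">", nrow(trk)))
    lines <- c(lines, sprintf("    <detection t=\"%d\" x=\"%.9g\" y=\"%.9g\" z=\"0\"/>",
                              trk$frame, trk$x, trk$y))
    lines <- c(lines, "  </particle>")
  }
  writeLines(c(lines, "</Tracks>"), path)
  path
}

# deterministic fixture vectors with K2 statistics frozen from an
# independent reference implementation of the D'Agostino-Pearson test
k2_reference_cases <- function() {
  list(
    list(x = sin(1:30) * 2 + (1:30) * 0.1,
         k2 = 1.1093348869638389, p = 0.5742632044166925),
    list(x = c(2.1, 1.9, 2.5, 2.2, 1.8, 2.0, 2.3, 1.7, 2.4, 2.6, 1.95,
               2.05, 2.15, 1.85, 2.45, 2.35, 1.75, 2.55, 2.25, 1.65),
         k2 = 2.9097891726464393, p = 0.23342496878849506),
    list(x = exp(seq(0, 2, length.out = 25)),
         k2 = 2.917256618714302, p = 0.23255504963503093)
  )
}

# small assay schedule shared across viability tests
demo_schedule <- function() {
  tibble::tibble(
    group = c(rep("NC", 6), "TX100_acute"),
    timepoint = c("acute", "1DIV", "4DIV", "7DIV", "11DIV", "14DIV", "acute"),
    mean = c(2.0, 1.6, 1.2, 1.4, 1.7, 1.9, 4.0),
    sd = 0, n_slices = 6
  )
}
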