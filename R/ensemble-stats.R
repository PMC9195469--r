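#' D'Agostino-Pearson omnibus K2 normality test
#'
#' Combines the D'Agostino skewness z-statistic and the Anscombe-Glynn
#' kurtosis z-statistic into `K2 = z_skew^2 + z_kurt^2`, referred to a
#' chi-squared distribution with 2 degrees of freedom. Requires at least 8
#' observations (the kurtosis normalization breaks down below that).
#'
#' @param x Numeric vector (n >= 8).
#' @return A one-row tibble: `statistic` (K2), `p.value`, `z_skew`,
#'   `z_kurt`, `n`.
#' @export
dagostino_k2 <- function(x) {
  x <- x[is.finite(x)]
  n <- length(x)
  if (n < 8) abort("D'Agostino-Pearson K2 requires at least 8 observations.")
  m <- mean(x)
  m2 <- mean((x - m)^2); m3 <- mean((x - m)^3); m4 <- mean((x - m)^4)
  g1 <- m3 / m2^1.5
  g2 <- m4 / m2^2

  # skewness (D'Agostino 1970)
  Y <- g1 * sqrt((n + 1) * (n + 3) / (6 * (n - 2)))
  b2 <- 3 * (n^2 + 27 * n - 70) * (n + 1) * (n + 3) /
    ((n - 2) * (n + 5) * (n + 7) * (n + 9))
  W2 <- -1 + sqrt(2 * (b2 - 1))
  delta <- 1 / sqrt(log(sqrt(W2)))
  a <- sqrt(2 / (W2 - 1))
  z1 <- delta * log(Y / a + sqrt((Y / a)^2 + 1))

  # kurtosis (Anscombe & Glynn 1983)
  Eb2 <- 3 * (n - 1) / (n + 1)
  Vb2 <- 24 * n * (n - 2) * (n - 3) / ((n + 1)^2 * (n + 3) * (n + 5))
  xk <- (g2 - Eb2) / sqrt(Vb2)
  sb <- 6 * (n^2 - 5 * n + 2) / ((n + 7) * (n + 9)) *
    sqrt(6 * (n + 3) * (n + 5) / (n * (n - 2) * (n - 3)))
  A <- 6 + 8 / sb * (2 / sb + sqrt(1 + 4 / sb^2))
  z2 <- ((1 - 2 / (9 * A)) -
           ((1 - 2 / A) / (1 + xk * sqrt(2 / (A - 4))))^(1 / 3)) /
    sqrt(2 / (9 * A))

  k2 <- z1^2 + z2^2
  tibble(statistic = k2, p.value = pchisq(k2, df = 2, lower.tail = FALSE),
         z_skew = z1, z_kurt = z2, n = n)
}

split_groups <- function(data, group, value) {
  g <- data[[group]]; v <- data[[value]]
  if (is.null(g) || is.null(v)) abort("`group`/`value` columns not found.")
  keep <- is.finite(v) & !is.na(g)
  g <- g[keep]; v <- v[keep]
  lv <- if (is.factor(g)) levels(droplevels(g)) else sort(unique(g))
  out <- lapply(lv, function(l) v[g == l])
  names(out) <- as.character(lv)
  out
}

# Brown-Forsythe (median-centered Levene) test for equal spread
bf_variance_test <- function(groups) {
  z <- lapply(groups, function(v) abs(v - median(v)))
  anova_f(z)
}

# ordinary one-way ANOVA on a list of numeric vectors
anova_f <- function(groups) {
  k <- length(groups)
  ni <- lengths(groups)
  N <- sum(ni)
  mi <- vapply(groups, mean, numeric(1))
  gm <- sum(ni * mi) / N
  ssb <- sum(ni * (mi - gm)^2)
  ssw <- sum(vapply(groups, function(v) sum((v - mean(v))^2), numeric(1)))
  f <- (ssb / (k - 1)) / (ssw / (N - k))
  list(statistic = f, df1 = k - 1, df2 = N - k,
       p.value = pf(f, k - 1, N - k, lower.tail = FALSE),
       mse = ssw / (N - k))
}

# Welch heteroscedastic one-way ANOVA
welch_anova <- function(groups) {
  ni <- lengths(groups)
  mi <- vapply(groups, mean, numeric(1))
  vi <- vapply(groups, var, numeric(1))
  wi <- ni / vi
  k <- length(groups)
  mw <- sum(wi * mi) / sum(wi)
  A <- sum(wi * (mi - mw)^2) / (k - 1)
  B <- 2 * (k - 2) / (k^2 - 1) *
    sum((1 - wi / sum(wi))^2 / (ni - 1))
  f <- A / (1 + B)
  df2 <- 1 / (3 / (k^2 - 1) * sum((1 - wi / sum(wi))^2 / (ni - 1)))
  list(statistic = f, df1 = k - 1, df2 = df2,
       p.value = pf(f, k - 1, df2, lower.tail = FALSE))
}

# Brown-Forsythe heteroscedastic ANOVA on means
bf_anova <- function(groups) {
  ni <- lengths(groups)
  N <- sum(ni)
  k <- length(groups)
  mi <- vapply(groups, mean, numeric(1))
  vi <- vapply(groups, var, numeric(1))
  gm <- sum(ni * mi) / N
  num <- sum(ni * (mi - gm)^2)
  ci <- (1 - ni / N) * vi
  f <- num / sum(ci)
  df2 <- sum(ci)^2 / sum(ci^2 / (ni - 1))
  list(statistic = f, df1 = k - 1, df2 = df2,
       p.value = pf(f, k - 1, df2, lower.tail = FALSE))
}

# Kruskal-Wallis H with tie correction
kruskal_h <- function(groups) {
  v <- unlist(groups, use.names = FALSE)
  g <- rep(seq_along(groups), lengths(groups))
  N <- length(v)
  r <- rank(v)
  ri <- tapply(r, g, mean)
  ni <- lengths(groups)
  H <- 12 / (N * (N + 1)) * sum(ni * (ri - (N + 1) / 2)^2)
  ties <- table(v)
  C <- 1 - sum(ties^3 - ties) / (N^3 - N)
  H <- H / C
  k <- length(groups)
  list(statistic = H, df1 = k - 1, df2 = NA_real_,
       p.value = pchisq(H, k - 1, lower.tail = FALSE))
}

#' Select the statistical comparison branch
#'
#' Reproduces the normality-gated decision tree used for group comparisons:
#' each group is tested for normality with the D'Agostino-Pearson omnibus K2
#' test; if any group rejects normality at `sig_level` the rank-based branch
#' (Kruskal-Wallis with Dunn post-hoc) is chosen. Otherwise equality of
#' spread is assessed with the Brown-Forsythe median-centered variance test:
#' rejection selects the heteroscedastic branch (Brown-Forsythe and Welch
#' ANOVA with Dunnett T3 post-hoc), acceptance the ordinary one-way ANOVA
#' with Tukey post-hoc. Groups smaller than 8 cannot be normality-tested and
#' force the rank-based branch with a note.
#'
#' @param data Data frame in long format.
#' @param group,value Column names (strings) of the group label and the
#'   numeric observation.
#' @param sig_level Significance level for every gate (default 0.05).
#' @return A `test_plan` object: list with `branch` (one of `anova_tukey`,
#'   `welch_brown_forsythe_dunnettT3`, `kruskal_dunn`), `normality` (tibble
#'   of per-group K2 results), `variance_homogeneity_p`, `sig_level`,
#'   `notes`.
#' @export
select_test_branch <- function(data, group = "group", value = "value",
                               sig_level = 0.05) {
  groups <- split_groups(data, group, value)
  if (length(groups) < 2) abort("at least 2 groups are required.")
  if (any(lengths(groups) < 3))
    abort("each group needs at least 3 observations.")
  notes <- character()
  small <- lengths(groups) < 8
  if (any(small)) {
    notes <- c(notes, paste0("group(s) ",
                             paste(names(groups)[small], collapse = ", "),
                             " have n < 8: normality cannot be assessed; ",
                             "falling back to the rank-based branch."))
    normality <- tibble(group = names(groups), n = lengths(groups),
                        statistic = NA_real_, p.value = NA_real_)
    plan <- list(branch = "kruskal_dunn", normality = normality,
                 variance_homogeneity_p = NA_real_, sig_level = sig_level,
                 notes = notes)
    return(structure(plan, class = "test_plan"))
  }
  normality <- purrr::imap(groups, function(v, nm) {
    r <- dagostino_k2(v)
    tibble(group = nm, n = r$n, statistic = r$statistic, p.value = r$p.value)
  }) %>% bind_rows()
  if (any(normality$p.value < sig_level)) {
    branch <- "kruskal_dunn"; var_p <- NA_real_
  } else {
    var_p <- bf_variance_test(groups)$p.value
    branch <- if (var_p < sig_level) "welch_brown_forsythe_dunnettT3"
    else "anova_tukey"
  }
  structure(list(branch = branch, normality = normality,
                 variance_homogeneity_p = var_p, sig_level = sig_level,
                 notes = notes),
            class = "test_plan")
}

#' @export
print.test_plan <- function(x, ...) {
  cat("<test_plan> branch:", x$branch, "\n")
  cat("  normality p (per group):",
      paste(sprintf("%s=%.3g", x$normality$group, x$normality$p.value),
            collapse = ", "), "\n")
  if (is.finite(x$variance_homogeneity_p))
    cat("  variance homogeneity p:",
        format(x$variance_homogeneity_p, digits = 3), "\n")
  for (nt in x$notes) cat("  note:", nt, "\n")
  invisible(x)
}

pair_grid <- function(nms, comparisons, reference) {
  idx <- utils::combn(seq_along(nms), 2)
  pairs <- tibble(group1 = nms[idx[1, ]], group2 = nms[idx[2, ]])
  if (comparisons == "vs_reference") {
    if (is.null(reference)) reference <- nms[1]
    if (!reference %in% nms) abort("`reference` is not a group label.")
    pairs <- pairs %>%
      filter(.data$group1 == reference | .data$group2 == reference)
  }
  pairs
}

#' Run the selected omnibus test and its named post-hoc procedure
#'
#' Executes the branch chosen by [select_test_branch()]: ordinary one-way
#' ANOVA with Tukey's studentized-range comparisons; Brown-Forsythe and
#' Welch ANOVA (Welch p reported as the omnibus p) with Dunnett T3
#' comparisons (Welch pairwise t statistics with Sidak family adjustment);
#' or Kruskal-Wallis (tie-corrected H) with Dunn's rank comparisons under a
#' Bonferroni family adjustment. Pairs are flagged significant when the
#' adjusted p-value falls below the plan's significance level.
#'
#' @inheritParams select_test_branch
#' @param plan A `test_plan` from [select_test_branch()]; `NULL` selects one
#'   from the data.
#' @param comparisons `"all_pairs"` (default) or `"vs_reference"`.
#' @param reference Reference group label for `vs_reference` (default:
#'   first group).
#' @return A `slice_comparison` object; [tidy()] returns the pairwise
#'   table, [glance()] a one-row omnibus summary.
#' @export
run_comparison <- function(data, group = "group", value = "value",
                           plan = NULL,
                           comparisons = c("all_pairs", "vs_reference"),
                           reference = NULL) {
  comparisons <- match.arg(comparisons)
  if (is.null(plan)) plan <- select_test_branch(data, group, value)
  if (!inherits(plan, "test_plan")) abort("`plan` must be a test_plan.")
  groups <- split_groups(data, group, value)
  if (!identical(sort(names(groups)), sort(plan$normality$group)))
    abort("`plan` was built on different group labels than `data`.")
  nms <- names(groups)
  ni <- lengths(groups)
  mi <- vapply(groups, mean, numeric(1))
  vi <- vapply(groups, var, numeric(1))
  pairs <- pair_grid(nms, comparisons, reference)
  m <- nrow(pairs)
  i1 <- match(pairs$group1, nms); i2 <- match(pairs$group2, nms)

  if (plan$branch == "anova_tukey") {
    om <- anova_f(groups)
    omnibus <- tibble(method = "one-way ANOVA", statistic = om$statistic,
                      df1 = om$df1, df2 = om$df2, p.value = om$p.value)
    se <- sqrt(om$mse / 2 * (1 / ni[i1] + 1 / ni[i2]))
    q <- abs(mi[i1] - mi[i2]) / se
    p_adj <- ptukey(q, length(nms), om$df2, lower.tail = FALSE)
    p_raw <- ptukey(q, 2, om$df2, lower.tail = FALSE)
    pw <- tibble(group1 = pairs$group1, group2 = pairs$group2,
                 estimate = unname(mi[i1] - mi[i2]), statistic = unname(q),
                 p.value = unname(p_raw), p.adjusted = unname(pmin(p_adj, 1)),
                 method = "Tukey HSD")
  } else if (plan$branch == "welch_brown_forsythe_dunnettT3") {
    w <- welch_anova(groups)
    bf <- bf_anova(groups)
    omnibus <- tibble(method = "Welch ANOVA (with Brown-Forsythe ANOVA)",
                      statistic = w$statistic, df1 = w$df1, df2 = w$df2,
                      p.value = w$p.value, bf_statistic = bf$statistic,
                      bf_p.value = bf$p.value)
    se <- sqrt(vi[i1] / ni[i1] + vi[i2] / ni[i2])
    tstat <- (mi[i1] - mi[i2]) / se
    dfw <- se^4 / ((vi[i1] / ni[i1])^2 / (ni[i1] - 1) +
                     (vi[i2] / ni[i2])^2 / (ni[i2] - 1))
    p_raw <- 2 * pt(-abs(tstat), dfw)
    p_adj <- 1 - (1 - p_raw)^m  # Sidak over the requested family
    pw <- tibble(group1 = pairs$group1, group2 = pairs$group2,
                 estimate = unname(mi[i1] - mi[i2]), statistic = unname(tstat),
                 p.value = unname(p_raw), p.adjusted = unname(pmin(p_adj, 1)),
                 method = "Dunnett T3 (Welch t, Sidak)")
  } else {
    kw <- kruskal_h(groups)
    omnibus <- tibble(method = "Kruskal-Wallis", statistic = kw$statistic,
                      df1 = kw$df1, df2 = NA_real_, p.value = kw$p.value)
    v <- unlist(groups, use.names = FALSE)
    gidx <- rep(seq_along(groups), ni)
    r <- rank(v)
    ri <- as.numeric(tapply(r, gidx, mean))
    N <- length(v)
    ties <- table(v)
    tiecor <- sum(ties^3 - ties) / (12 * (N - 1))
    sigma <- sqrt((N * (N + 1) / 12 - tiecor) *
                    (1 / ni[i1] + 1 / ni[i2]))
    z <- (ri[i1] - ri[i2]) / sigma
    p_raw <- 2 * pnorm(-abs(z))
    p_adj <- pmin(p_raw * m, 1)  # Bonferroni-style family adjustment
    pw <- tibble(group1 = pairs$group1, group2 = pairs$group2,
                 estimate = unname(ri[i1] - ri[i2]), statistic = unname(z),
                 p.value = unname(p_raw), p.adjusted = unname(p_adj),
                 method = "Dunn (Bonferroni)")
  }
  pw$significant <- pw$p.adjusted < plan$sig_level
  structure(list(branch = plan$branch, omnibus = omnibus, pairwise = pw,
                 plan = plan, comparisons = comparisons,
                 sig_level = plan$sig_level),
            class = "slice_comparison")
}

#' @method tidy slice_comparison
#' @export
tidy.slice_comparison <- function(x, ...) x$pairwise

#' @method glance slice_comparison
#' @export
glance.slice_comparison <- function(x, ...) {
  dplyr::bind_cols(tibble(branch = x$branch), x$omnibus[1, ])
}

#' @export
print.slice_comparison <- function(x, ...) {
  cat("<slice_comparison> branch:", x$branch, "\n")
  cat("  omnibus:", x$omnibus$method[1], " p =",
      format(x$omnibus$p.value[1], digits = 4), "\n")
  print(x$pairwise)
  invisible(x)
}
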