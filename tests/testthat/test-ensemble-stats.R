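test_that("K2 normality test matches an independent reference implementation", {
  for (case in k2_reference_cases()) {
    r <- dagostino_k2(case$x)
    expect_equal(r$statistic, case$k2, tolerance = 1e-10)
    expect_equal(r$p.value, case$p, tolerance = 1e-10)
  }
  expect_error(dagostino_k2(rnorm(7)), "at least 8")
})

test_that("omnibus statistics agree with the standard-library implementations", {
  set.seed(42)
  d <- data.frame(group = rep(c("a", "b", "c"), times = c(12, 15, 18)),
                  value = c(rnorm(12), rnorm(15, 0.5, 2), rnorm(18, 1)))
  gl <- split(d$value, d$group)

  a <- slicetrack:::anova_f(gl)
  av <- anova(stats::aov(value ~ group, d))
  expect_equal(a$statistic, av$`F value`[1], tolerance = 1e-10)

  w <- slicetrack:::welch_anova(gl)
  ow <- stats::oneway.test(value ~ group, d)
  expect_equal(w$statistic, unname(ow$statistic), tolerance = 1e-10)
  expect_equal(w$df2, unname(ow$parameter[2]), tolerance = 1e-8)
  expect_equal(w$p.value, ow$p.value, tolerance = 1e-10)

  k <- slicetrack:::kruskal_h(gl)
  kt <- stats::kruskal.test(value ~ group, d)
  expect_equal(k$statistic, unname(kt$statistic), tolerance = 1e-10)

  lv <- slicetrack:::bf_variance_test(gl)
  cv <- car::leveneTest(value ~ factor(group), d, center = median)
  expect_equal(lv$statistic, cv$`F value`[1], tolerance = 1e-10)
  expect_equal(lv$p.value, cv$`Pr(>F)`[1], tolerance = 1e-10)

  plan <- select_test_branch(d)
  rc <- run_comparison(d, plan = plan)
  if (plan$branch == "anova_tukey") {
    th <- stats::TukeyHSD(stats::aov(value ~ group, d))$group
    expect_equal(tidy(rc)$p.adjusted, unname(th[, "p adj"]),
                 tolerance = 1e-8)
  }
})

test_that("branch selection is a pure function of the data", {
  set.seed(7)
  d <- data.frame(group = rep(c("g1", "g2", "g3"), each = 30),
                  value = rnorm(90))
  p1 <- select_test_branch(d); p2 <- select_test_branch(d)
  expect_identical(p1$branch, p2$branch)
  expect_equal(p1$normality, p2$normality)
  expect_error(select_test_branch(d[d$group == "g1", ]), "2 groups")
  small <- data.frame(group = rep(c("a", "b"), each = 4),
                      value = rnorm(8))
  ps <- select_test_branch(small)
  expect_identical(ps$branch, "kruskal_dunn")
  expect_match(ps$notes[1], "n < 8")
})

test_that("simulated sampling distributions route to the expected branches", {
  withr::local_seed(1001)
  reps <- 40
  hit <- c(g = 0, l = 0, h = 0)
  for (r in seq_len(reps)) {
    g <- data.frame(group = rep(c("a", "b", "c"), each = 30),
                    value = rnorm(90, 5, 1))
    l <- data.frame(group = rep(c("a", "b", "c"), each = 30),
                    value = exp(rnorm(90, 0, 0.83)))  # sd/mean ~ 1
    h <- data.frame(group = rep(c("a", "b", "c"), each = 30),
                    value = rnorm(90, 5, rep(c(1, 1, 5), each = 30)))
    hit["g"] <- hit["g"] + (select_test_branch(g)$branch == "anova_tukey")
    hit["l"] <- hit["l"] + (select_test_branch(l)$branch == "kruskal_dunn")
    hit["h"] <- hit["h"] +
      (select_test_branch(h)$branch == "welch_brown_forsythe_dunnettT3")
  }
  # the Gaussian branch rate is bounded by the nominal gate sizes:
  # three 5% normality gates and one 5% variance gate give ~0.80
  expect_gte(hit[["g"]] / reps, 0.6)
  expect_gte(hit[["l"]] / reps, 0.9)
  expect_gte(hit[["h"]] / reps, 0.65)
})

test_that("identical groups give a null comparison; adjustment is monotone; labels permute", {
  d0 <- data.frame(group = rep(c("a", "b"), each = 10),
                   value = rep(seq(1, 3, length.out = 10), 2))
  rc0 <- run_comparison(d0)
  expect_gt(glance(rc0)$p.value, 0.999)
  expect_false(any(tidy(rc0)$significant))

  set.seed(99)
  for (branch_data in list(
    data.frame(group = rep(c("a", "b", "c"), each = 30),
               value = rnorm(90)),
    data.frame(group = rep(c("a", "b", "c"), each = 30),
               value = exp(rnorm(90))))) {
    rc <- run_comparison(branch_data)
    expect_true(all(tidy(rc)$p.adjusted >= tidy(rc)$p.value - 1e-12))
    # permutation symmetry: relabel and compare matched pairs
    perm <- branch_data
    perm$group <- c(a = "b", b = "c", c = "a")[perm$group]
    rcp <- run_comparison(perm)
    key <- function(g1, g2) purrr::map2_chr(g1, g2,
                                            ~paste(sort(c(.x, .y)),
                                                   collapse = "-"))
    relab <- c(a = "b", b = "c", c = "a")
    m <- match(key(relab[tidy(rc)$group1], relab[tidy(rc)$group2]),
               key(tidy(rcp)$group1, tidy(rcp)$group2))
    expect_equal(tidy(rc)$p.adjusted, tidy(rcp)$p.adjusted[m],
                 tolerance = 1e-10)
  }
})

test_that("power and error control behave sensibly on Gaussian groups", {
  withr::local_seed(2024)
  reps <- 30
  power_hit <- 0; null_flag <- 0
  for (r in seq_len(reps)) {
    d <- data.frame(group = rep(c("a", "b", "c"), each = 30),
                    value = c(rnorm(30, 0), rnorm(30, 0), rnorm(30, 3)))
    rc <- run_comparison(d)
    pw <- tidy(rc)
    ac <- pw$significant[(pw$group1 == "a" & pw$group2 == "c") |
                           (pw$group1 == "c" & pw$group2 == "a")]
    ab <- pw$significant[(pw$group1 == "a" & pw$group2 == "b") |
                           (pw$group1 == "b" & pw$group2 == "a")]
    power_hit <- power_hit + (ac && !ab)

    d0 <- data.frame(group = rep(c("a", "b", "c"), each = 30),
                     value = rnorm(90))
    null_flag <- null_flag + any(tidy(run_comparison(d0))$significant)
  }
  expect_gte(power_hit / reps, 0.9)
  expect_lte(null_flag / reps, 0.2)  # coarse small-sample FWER bound
})

test_that("vs-reference mode restricts the family of comparisons", {
  set.seed(5)
  d <- data.frame(group = rep(c("NC", "ogd1", "ogd2", "ogd3"), each = 30),
                  value = rnorm(120))
  rc <- run_comparison(d, comparisons = "vs_reference", reference = "NC")
  pw <- tidy(rc)
  expect_equal(nrow(pw), 3)
  expect_true(all(pw$group1 == "NC" | pw$group2 == "NC"))
  expect_error(run_comparison(d, comparisons = "vs_reference",
                              reference = "nope"), "not a group")
})
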