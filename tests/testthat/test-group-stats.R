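crops_df <- function(...) tibble::tibble(...)

test_that("per-mouse aggregation uses mean for densities, pooled sums for percentages", {
  crops <- crops_df(
    mouse = "m1", genotype = "tg", age_group = "9", crop = 1:3,
    n_pre = c(20, 30, 40), n_gfp_pre = c(2, 3, 4),
    n_post = c(10, 90, 0), n_post_tau = c(1, 1, 0),
    n_pairs = c(0, 0, 0), n_pairs_tau = c(0, 0, 0),
    volume_um3 = 100)
  m <- aggregate_mice(crops)
  expect_equal(m$density_pre_um3, mean(c(0.2, 0.3, 0.4)))
  # (1/10, 1/90) pools to 2/100 = 2 percent, not the 5.56 mean of ratios
  expect_equal(m$pct_post_tau, 2)
  expect_true(is.na(m$pct_pairs_tau))   # zero denominator -> missing
  single <- aggregate_mice(crops[1, ])
  expect_equal(single$density_pre_um3, 0.2)
  expect_equal(single$pct_post_tau, 10)
})

test_that("Kruskal-Wallis reproduces hand-computed rank statistics", {
  d <- tibble::tibble(y = 1:9, g = rep(c("a", "b", "c"), each = 3))
  fit <- kruskal_wallis(d, "y", "g")
  expect_equal(fit$statistic, 7.2, tolerance = 1e-12)
  expect_equal(fit$df, 2)
  # {1,3} vs {2,4}: H = 0.6 by direct rank-sum arithmetic
  d2 <- tibble::tibble(y = c(1, 3, 2, 4), g = c("a", "a", "b", "b"))
  expect_equal(kruskal_wallis(d2, "y", "g")$statistic, 0.6, tolerance = 1e-12)
})

test_that("Kruskal-Wallis agrees with the reference implementation, ties included", {
  set.seed(123)
  for (i in 1:20) {
    y <- sample(1:6, 15, replace = TRUE)  # heavy ties
    g <- sample(c("a", "b", "c"), 15, replace = TRUE)
    if (length(unique(g)) < 2) next
    d <- tibble::tibble(y = y, g = g)
    fit <- kruskal_wallis(d, "y", "g")
    ref <- stats::kruskal.test(y, factor(g))
    expect_equal(fit$statistic, unname(ref$statistic), tolerance = 1e-10)
    expect_equal(fit$p.value, ref$p.value, tolerance = 1e-10)
  }
})

test_that("H is invariant under strictly monotone transforms and within-group permutation", {
  set.seed(31)
  y <- rnorm(18); g <- rep(c("a", "b", "c"), each = 6)
  h0 <- kruskal_wallis(tibble::tibble(y = y, g = g), "y", "g")$statistic
  expect_equal(kruskal_wallis(tibble::tibble(y = exp(y), g = g), "y", "g")$statistic, h0)
  expect_equal(kruskal_wallis(tibble::tibble(y = 3 * y - 7, g = g), "y", "g")$statistic, h0)
  yp <- ave(y, g, FUN = sample)
  expect_equal(kruskal_wallis(tibble::tibble(y = yp, g = g), "y", "g")$statistic, h0)
})

test_that("identical observations give H = 0 with p = 1", {
  d <- tibble::tibble(y = rep(5, 9), g = rep(c("a", "b", "c"), each = 3))
  fit <- kruskal_wallis(d, "y", "g")
  expect_equal(fit$statistic, 0)
  expect_equal(fit$p.value, 1)
})

balanced_df <- function(y) {
  tibble::tibble(y = y,
                 genotype = rep(c("tg", "ctl"), each = 9),
                 age_group = rep(rep(c("3-6", "9", "18"), each = 3), 2))
}

test_that("all-equal observations give zero effect sums of squares", {
  fit <- two_way_anova(balanced_df(rep(4, 18)), "y")
  expect_equal(fit$terms$sumsq[1:3], c(0, 0, 0))
})

test_that("a pure genotype shift loads only the genotype term", {
  delta <- 2
  base <- rep(1, 18)
  d <- balanced_df(base + ifelse(rep(c(TRUE, FALSE), each = 9), delta, 0))
  fit <- two_way_anova(d, "y")
  # brute-force from cell means: SS_A = b*r*sum((mean_i - grand)^2)
  expect_equal(fit$terms$sumsq[1], 3 * 3 * 2 * (delta / 2)^2, tolerance = 1e-12)
  expect_equal(fit$terms$sumsq[2], 0, tolerance = 1e-12)
  expect_equal(fit$terms$sumsq[3], 0, tolerance = 1e-12)
  expect_equal(fit$terms$sumsq[4], 0, tolerance = 1e-12)
})

test_that("the balanced decomposition sums exactly to total SS", {
  set.seed(71)
  for (i in 1:10) {
    d <- balanced_df(rnorm(18))
    fit <- two_way_anova(d, "y")
    ss_total <- sum((d$y - mean(d$y))^2)
    expect_equal(sum(fit$terms$sumsq), ss_total, tolerance = 1e-10 * ss_total)
  }
})

test_that("ANOVA agrees with the reference implementations", {
  set.seed(81)
  d <- balanced_df(rnorm(18, sd = 2))
  fit <- two_way_anova(d, "y")
  ref <- summary(stats::aov(y ~ genotype * age_group, data = d))[[1]]
  expect_equal(fit$terms$sumsq, unname(ref[["Sum Sq"]]), tolerance = 1e-10)
  expect_equal(fit$terms$statistic[1:3], unname(ref[["F value"]][1:3]),
               tolerance = 1e-10)
  # unbalanced: Type-II sums of squares against car::Anova
  du <- d[-c(1, 2, 10), ]
  fitu <- two_way_anova(du, "y")
  refu <- car::Anova(stats::lm(y ~ genotype * age_group, data = du), type = 2)
  expect_equal(fitu$terms$sumsq, unname(refu[["Sum Sq"]]), tolerance = 1e-10)
  expect_equal(fitu$terms$p.value[1:3], unname(refu[["Pr(>F)"]][1:3]),
               tolerance = 1e-10)
  expect_match(fitu$ss_type, "Type II")
})

test_that("an empty design cell is a named failure", {
  d <- balanced_df(rnorm(18))
  d <- d[!(d$genotype == "ctl" & d$age_group == "18"), ]
  expect_error(two_way_anova(d, "y"), "empty design cell.*ctl.*18")
})

test_that("tidy and glance return broom-shaped tables", {
  d <- balanced_df(rnorm(18))
  fit <- two_way_anova(d, "y")
  td <- tidy(fit)
  expect_s3_class(td, "tbl_df")
  expect_named(td, c("term", "df", "sumsq", "meansq", "statistic", "p.value"))
  expect_equal(nrow(td), 4)
  gl <- glance(fit)
  expect_equal(gl$n, 18)
  kw <- kruskal_wallis(tibble::tibble(y = 1:9, g = rep(letters[1:3], 3)),
                       "y", "g")
  expect_named(tidy(kw), c("statistic", "df", "p.value", "n", "method"))
})

test_that("normality gate drives the automatic branch choice", {
  set.seed(40)  # pinned: a clean normal sample
  d <- balanced_df(rnorm(18))
  expect_gt(shapiro_normality(d$y)$p.value, 0.05)
  fit <- compare_groups(d, "y")
  expect_s3_class(fit, "synaptomo_anova")
  expect_equal(attr(fit, "branch"), "anova")
  set.seed(41)  # pinned: heavy right skew
  ds <- balanced_df(exp(3 * rnorm(18)))
  expect_lt(shapiro_normality(ds$y)$p.value, 0.05)
  fits <- compare_groups(ds, "y")
  expect_s3_class(fits, "synaptomo_kw")
  # explicit override mirrors a predetermined analysis plan
  expect_s3_class(compare_groups(ds, "y", branch = "anova"),
                  "synaptomo_anova")
  expect_error(shapiro_normality(c(1, 2)), "at least 3")
  expect_error(shapiro_normality(rep(2, 10)), "variance")
})
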