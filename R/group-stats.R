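#' Aggregate crop-level measurements to one row per mouse
#'
#' Applies the two per-mouse aggregation rules used throughout the
#' analysis: density-type statistics are averaged over a mouse's crops
#' (they are normally distributed across crops), while percentage-type
#' statistics are pooled by sums — total positive counts over total object
#' counts across crops — never by averaging per-crop percentages. A mouse
#' whose pooled denominator is zero gets a missing value for that
#' percentage.
#'
#' @param crops Tibble with one row per crop: identifiers `mouse`,
#'   `genotype`, `age_group`, counts `n_pre`, `n_gfp_pre`, `n_post`,
#'   `n_post_tau`, `n_pairs`, `n_pairs_tau`, and `volume_um3`.
#' @return Tibble with one row per mouse: densities (`density_pre_um3`,
#'   `density_gfp_pre_um3`, mean over crops) and pooled percentages
#'   (`pct_gfp_pre`, `pct_post_tau`, `pct_pairs_tau`).
#' @export
aggregate_mice <- function(crops) {
  stopifnot(all(c("mouse", "genotype", "age_group", "n_pre", "n_gfp_pre",
                  "n_post", "n_post_tau", "n_pairs", "n_pairs_tau",
                  "volume_um3") %in% names(crops)))
  pooled_pct <- function(num, den) {
    if (sum(den) == 0) NA_real_ else 100 * sum(num) / sum(den)
  }
  crops |>
    dplyr::group_by(.data$mouse, .data$genotype, .data$age_group) |>
    dplyr::summarise(
      n_crops = dplyr::n(),
      density_pre_um3 = mean(.data$n_pre / .data$volume_um3),
      density_gfp_pre_um3 = mean(.data$n_gfp_pre / .data$volume_um3),
      pct_gfp_pre = pooled_pct(.data$n_gfp_pre, .data$n_pre),
      pct_post_tau = pooled_pct(.data$n_post_tau, .data$n_post),
      pct_pairs_tau = pooled_pct(.data$n_pairs_tau, .data$n_pairs),
      .groups = "drop")
}

#' Two-way analysis of variance from the classical decomposition
#'
#' Fits the two-factor crossed model. On balanced designs the classical
#' decomposition `SS_total = SS_A + SS_B + SS_AB + SS_error` is computed
#' directly from cell and marginal means; on unbalanced designs Type-II
#' sums of squares are used (each main effect adjusted for the other,
#' interaction adjusted for both), computed from residual sums of squares
#' of the nested least-squares fits. F statistics test each term against
#' the within-cell error.
#'
#' @param data Data frame of per-mouse values.
#' @param response,factor_a,factor_b Column names (strings) of the response
#'   and the two factors (conventionally genotype and age group).
#' @return Object of class `synaptomo_anova`; see [tidy.synaptomo_anova()].
#' @export
two_way_anova <- function(data, response, factor_a = "genotype",
                          factor_b = "age_group") {
  y <- data[[response]]
  A <- factor(data[[factor_a]])
  B <- factor(data[[factor_b]])
  keep <- stats::complete.cases(y, A, B)
  y <- y[keep]; A <- droplevels(A[keep]); B <- droplevels(B[keep])
  if (nlevels(A) < 2 || nlevels(B) < 2) {
    stop("each factor needs at least two levels", call. = FALSE)
  }
  counts <- table(A, B)
  if (any(counts == 0)) {
    bad <- which(counts == 0, arr.ind = TRUE)[1, ]
    stop(sprintf("empty design cell: %s = %s, %s = %s",
                 factor_a, rownames(counts)[bad[1]],
                 factor_b, colnames(counts)[bad[2]]), call. = FALSE)
  }
  N <- length(y)
  a <- nlevels(A); b <- nlevels(B)
  df_a <- a - 1; df_b <- b - 1; df_ab <- df_a * df_b
  df_err <- N - a * b
  cell_mean <- tapply(y, list(A, B), mean)
  ss_err <- sum((y - cell_mean[cbind(A, B)])^2)
  balanced <- length(unique(as.vector(counts))) == 1
  if (balanced) {
    r <- counts[1, 1]
    gm <- mean(y)
    ma <- tapply(y, A, mean); mb <- tapply(y, B, mean)
    ss_a <- b * r * sum((ma - gm)^2)
    ss_b <- a * r * sum((mb - gm)^2)
    inter <- sweep(sweep(cell_mean, 1, ma), 2, mb) + gm
    ss_ab <- r * sum(inter^2)
    ss_type <- "classical (balanced)"
  } else {
    rss <- function(form) sum(stats::lm(form, data = data.frame(y, A, B))$residuals^2)
    rss_ab_add <- rss(y ~ A + B)
    ss_a <- rss(y ~ B) - rss_ab_add
    ss_b <- rss(y ~ A) - rss_ab_add
    ss_ab <- rss_ab_add - rss(y ~ A * B)
    ss_type <- "Type II (unbalanced)"
  }
  ms_err <- if (df_err > 0) ss_err / df_err else NA_real_
  term_tbl <- tibble::tibble(
    term = c(factor_a, factor_b, paste0(factor_a, ":", factor_b), "Residuals"),
    df = c(df_a, df_b, df_ab, df_err),
    sumsq = c(ss_a, ss_b, ss_ab, ss_err))
  term_tbl$meansq <- term_tbl$sumsq / term_tbl$df
  term_tbl$statistic <- c(term_tbl$meansq[1:3] / ms_err, NA_real_)
  term_tbl$p.value <- c(stats::pf(term_tbl$statistic[1:3],
                                  term_tbl$df[1:3], df_err,
                                  lower.tail = FALSE), NA_real_)
  structure(
    list(terms = term_tbl, response = response, n = N, ss_type = ss_type,
         factors = c(factor_a, factor_b)),
    class = "synaptomo_anova")
}

#' @export
print.synaptomo_anova <- function(x, ...) {
  cat(sprintf("Two-way ANOVA of %s (%s), n = %d\n", x$response, x$ss_type, x$n))
  print(as.data.frame(x$terms), row.names = FALSE)
  invisible(x)
}

#' Tidy a two-way ANOVA result
#' @param x A `synaptomo_anova`.
#' @param ... Unused.
#' @return Tibble with one row per model term: `term`, `df`, `sumsq`,
#'   `meansq`, `statistic`, `p.value`.
#' @exportS3Method generics::tidy
#' @export
tidy.synaptomo_anova <- function(x, ...) x$terms

#' @rdname tidy.synaptomo_anova
#' @exportS3Method generics::glance
#' @export
glance.synaptomo_anova <- function(x, ...) {
  tibble::tibble(n = x$n, ss_type = x$ss_type,
                 p_a = x$terms$p.value[1], p_b = x$terms$p.value[2],
                 p_interaction = x$terms$p.value[3])
}

#' Kruskal-Wallis rank-sum test from the defining formula
#'
#' Nonparametric comparison of two or more independent groups:
#' `H = 12 / (N (N + 1)) * sum(R_i^2 / n_i) - 3 (N + 1)` over mid-ranks,
#' divided by the standard tie correction `1 - sum(t^3 - t) / (N^3 - N)`.
#' The p-value uses the chi-square approximation with `k - 1` degrees of
#' freedom. When every observation is identical the tie correction
#' degenerates; by convention `H = 0` with `p = 1`.
#'
#' @param data Data frame of per-mouse values.
#' @param response,group Column names (strings) of the response and the
#'   grouping factor.
#' @return Object of class `synaptomo_kw`; see [tidy.synaptomo_kw()].
#' @export
kruskal_wallis <- function(data, response, group) {
  y <- data[[response]]
  g <- factor(data[[group]])
  keep <- stats::complete.cases(y, g)
  y <- y[keep]; g <- droplevels(g[keep])
  k <- nlevels(g)
  if (k < 2 || any(table(g) == 0)) {
    stop("need at least two non-empty groups", call. = FALSE)
  }
  N <- length(y)
  rk <- rank(y)            # mid-ranks for ties
  Ri <- tapply(rk, g, sum)
  ni <- tapply(rk, g, length)
  H_raw <- 12 / (N * (N + 1)) * sum(Ri^2 / ni) - 3 * (N + 1)
  ties <- table(y)
  corr <- 1 - sum(ties^3 - ties) / (N^3 - N)
  H <- if (corr <= 0) 0 else H_raw / corr
  p <- if (corr <= 0) 1 else stats::pchisq(H, df = k - 1, lower.tail = FALSE)
  structure(
    list(statistic = H, df = k - 1, p.value = p, n = N, k = k,
         tie_correction = corr, response = response, group = group),
    class = "synaptomo_kw")
}

#' @export
print.synaptomo_kw <- function(x, ...) {
  cat(sprintf(
    "Kruskal-Wallis: %s by %s, H = %.4g, df = %d, p = %.4g (n = %d)\n",
    x$response, x$group, x$statistic, x$df, x$p.value, x$n))
  invisible(x)
}

#' Tidy a Kruskal-Wallis result
#' @param x A `synaptomo_kw`.
#' @param ... Unused.
#' @return One-row tibble: `statistic`, `df`, `p.value`, `n`, `method`.
#' @exportS3Method generics::tidy
#' @export
tidy.synaptomo_kw <- function(x, ...) {
  tibble::tibble(statistic = x$statistic, df = x$df, p.value = x$p.value,
                 n = x$n, method = "Kruskal-Wallis (tie-corrected)")
}

#' @rdname tidy.synaptomo_kw
#' @exportS3Method generics::glance
#' @export
glance.synaptomo_kw <- function(x, ...) tidy(x)

#' Shapiro-Wilk normality check
#'
#' Used to choose between the parametric and nonparametric branch of the
#' group comparison at `alpha = 0.05`; the branch is overridable so users
#' can mirror a predetermined analysis plan exactly.
#'
#' @param values Numeric vector, `n >= 3`, non-constant.
#' @return List with `statistic` (W) and `p.value`.
#' @export
shapiro_normality <- function(values) {
  values <- values[!is.na(values)]
  if (length(values) < 3) stop("need at least 3 values", call. = FALSE)
  if (stats::sd(values) == 0) stop("zero variance: normality undefined",
                                   call. = FALSE)
  s <- stats::shapiro.test(values)
  list(statistic = unname(s$statistic), p.value = s$p.value)
}

#' Compare groups, choosing the test branch
#'
#' `branch = "auto"` runs Shapiro-Wilk on the pooled per-mouse values and
#' picks the two-way ANOVA when `p > alpha`, otherwise Kruskal-Wallis on
#' `group`; the decision is recorded in the result. Explicit branches skip
#' the normality gate.
#'
#' @param data Per-mouse data frame.
#' @param response Response column name.
#' @param factor_a,factor_b Factors for the ANOVA branch.
#' @param group Grouping column for the Kruskal-Wallis branch (defaults to
#'   `factor_b`, the age group).
#' @param branch `"auto"`, `"anova"` or `"kruskal"`.
#' @param alpha Normality significance level for the automatic branch.
#' @return The fitted `synaptomo_anova` or `synaptomo_kw`, with attributes
#'   `branch` and `shapiro_p` (the latter only for `"auto"`).
#' @export
compare_groups <- function(data, response, factor_a = "genotype",
                           factor_b = "age_group", group = factor_b,
                           branch = c("auto", "anova", "kruskal"),
                           alpha = 0.05) {
  branch <- match.arg(branch)
  shapiro_p <- NA_real_
  if (branch == "auto") {
    shapiro_p <- shapiro_normality(data[[response]])$p.value
    branch <- if (shapiro_p > alpha) "anova" else "kruskal"
  }
  fit <- if (branch == "anova") {
    two_way_anova(data, response, factor_a, factor_b)
  } else {
    kruskal_wallis(data, response, group)
  }
  attr(fit, "branch") <- branch
  attr(fit, "shapiro_p") <- shapiro_p
  fit
}
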