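# ---------------------------------------------------------------------------
# Statistical primitives: pooled and paired t-tests with explicit
# zero-variance conventions, Bonferroni families, two-factor ANOVA with
# Type II sums of squares and nested block terms, simple main effects with a
# Scheffe-type simultaneous critical value, and exact binomial mass.
# ---------------------------------------------------------------------------

test_result <- function(statistic, df, p, alpha = 0.05, family_m = 1L) {
  thr <- bonferroni(alpha, family_m)
  list(statistic = statistic, df = df, p = p,
       family_m = family_m, threshold = thr, significant = p < thr)
}

#' Pooled-variance two-sample t-test
#'
#' Classical equal-variance two-sample t with `df = n_x + n_y - 2` and a
#' two-sided p-value.  Zero pooled variance is handled by convention rather
#' than error (noiseless synthetic data hits it): equal means give `t = 0`,
#' `p = 1`; unequal means give an infinite t and `p = 0`.
#'
#' @param x,y numeric samples (each of length >= 2).
#' @param alpha family-wise alpha.
#' @param family_m Bonferroni family size.
#' @return list: statistic, df, p, family_m, threshold, significant.
#' @export
pooled_two_sample_t <- function(x, y, alpha = 0.05, family_m = 1L) {
  nx <- length(x); ny <- length(y)
  if (nx < 2L || ny < 2L) stop("each sample needs at least 2 observations")
  df <- nx + ny - 2L
  sp2 <- ((nx - 1) * stats::var(x) + (ny - 1) * stats::var(y)) / df
  dm <- mean(x) - mean(y)
  if (sp2 <= 0) {
    if (dm == 0) return(test_result(0, df, 1, alpha, family_m))
    return(test_result(sign(dm) * Inf, df, 0, alpha, family_m))
  }
  t <- dm / sqrt(sp2 * (1 / nx + 1 / ny))
  test_result(t, df, 2 * stats::pt(-abs(t), df), alpha, family_m)
}

one_sample_t <- function(x, mu = 0, alpha = 0.05, family_m = 1L) {
  n <- length(x)
  if (n < 2L) stop("need at least 2 observations")
  df <- n - 1L
  s2 <- stats::var(x)
  dm <- mean(x) - mu
  if (s2 <= 0) {
    if (dm == 0) return(test_result(0, df, 1, alpha, family_m))
    return(test_result(sign(dm) * Inf, df, 0, alpha, family_m))
  }
  t <- dm / sqrt(s2 / n)
  test_result(t, df, 2 * stats::pt(-abs(t), df), alpha, family_m)
}

#' Paired-samples t-test
#'
#' One-sample t on the within-pair differences, `df = n - 1`, two-sided.
#' Zero-variance differences follow the same conventions as
#' [pooled_two_sample_t()].
#'
#' @param x,y paired numeric samples of equal length >= 2.
#' @param alpha family-wise alpha.
#' @param family_m Bonferroni family size.
#' @return list: statistic, df, p, family_m, threshold, significant.
#' @export
paired_t <- function(x, y, alpha = 0.05, family_m = 1L) {
  if (length(x) != length(y)) stop("paired samples must have equal length")
  one_sample_t(x - y, mu = 0, alpha = alpha, family_m = family_m)
}

#' Bonferroni-adjusted threshold
#'
#' `alpha / m`: 0.05 over 20 tests gives 2.5e-3; over 3 tests, 0.0167.
#'
#' @param alpha family-wise alpha in (0, 1).
#' @param m number of tests (>= 1).
#' @return adjusted per-test threshold.
#' @export
bonferroni <- function(alpha, m) {
  stopifnot(m >= 1, alpha > 0, alpha < 1)
  alpha / m
}

#' Two-factor ANOVA with nested block terms
#'
#' Fixed-effects least-squares decomposition with main effects of the two
#' factors, their interaction, and optional cohort and subject-within-cohort
#' block terms, using Type II sums of squares (the common default for
#' main-effect inference without a priori interaction emphasis).  F ratios
#' use the residual mean square.
#'
#' @param data data.frame containing the model columns.
#' @param response column name of the numeric response.
#' @param factor_a,factor_b column names of the two crossed factors.
#' @param cohort,subject optional column names for the block terms
#'   (`subject` is modelled nested within `cohort`).
#' @return list of class `anova_table`: `table` (data.frame with term, ss,
#'   df, ms, f, p), `fit` (the underlying lm), `residual_df`,
#'   `residual_ms`, plus the factor names.
#' @export
two_factor_anova <- function(data, response, factor_a, factor_b,
                             cohort = NULL, subject = NULL) {
  for (v in c(factor_a, factor_b, cohort, subject))
    data[[v]] <- factor(data[[v]])
  if (nlevels(data[[factor_a]]) < 2L || nlevels(data[[factor_b]]) < 2L)
    stop("both factors need at least 2 levels")
  terms <- c(paste(factor_a, factor_b, sep = " * "))
  if (!is.null(cohort)) {
    terms <- c(terms, cohort)
    if (!is.null(subject))
      terms <- c(terms, paste0(cohort, ":", subject))
  } else if (!is.null(subject)) terms <- c(terms, subject)
  fml <- stats::as.formula(paste(response, "~", paste(terms, collapse = " + ")))
  fit <- stats::lm(fml, data = data)
  if (any(is.na(stats::coef(fit)))) {
    bad <- names(stats::coef(fit))[is.na(stats::coef(fit))]
    stop("rank-deficient design; aliased terms: ",
         paste(utils::head(bad, 5), collapse = ", "))
  }
  rss <- sum(stats::residuals(fit)^2)
  tss <- sum((data[[response]] - mean(data[[response]]))^2)
  if (rss > max(tss, 1) * 1e-12) {
    a2 <- car::Anova(fit, type = 2)
    tab <- data.frame(term = rownames(a2), ss = a2[["Sum Sq"]],
                      df = a2[["Df"]], f = a2[["F value"]],
                      p = a2[["Pr(>F)"]], row.names = NULL)
  } else {
    # degenerate zero-residual fit (noiseless synthetic data): sequential
    # SS (equal to Type II here), with the 0/0 convention F = 0, p = 1
    a1 <- suppressWarnings(stats::anova(fit))
    ss <- a1[["Sum Sq"]]
    tab <- data.frame(term = rownames(a1), ss = ss, df = a1[["Df"]],
                      f = ifelse(ss <= max(tss, 1) * 1e-12, 0, Inf),
                      p = ifelse(ss <= max(tss, 1) * 1e-12, 1, 0),
                      row.names = NULL)
    tab$f[tab$term == "Residuals"] <- NA
    tab$p[tab$term == "Residuals"] <- NA
  }
  res <- tab$term == "Residuals"
  tab$ms <- tab$ss / tab$df
  structure(list(table = tab, fit = fit,
                 residual_df = tab$df[res], residual_ms = tab$ms[res],
                 factor_a = factor_a, factor_b = factor_b,
                 response = response),
            class = "anova_table")
}

#' Simple main effects with a simultaneous critical value
#'
#' Tests the effect of one factor at each fixed level of the other, using
#' the full model's pooled residual mean square as the error term.
#' Significance is judged against the Scheffe-type simultaneous critical
#' value `F* = (a - 1) F(alpha; a - 1, df_res)`, where `a` is the tested
#' factor's number of levels — a conservative bound for the family of
#' slices.
#'
#' @param fit an [two_factor_anova()] result.
#' @param factor which factor to test (`factor_a` or `factor_b` name).
#' @param alpha simultaneous alpha (default 0.05).
#' @return data.frame: level of the other factor, ss, df, f, f_crit,
#'   significant, p (nominal, vs the pooled error).
#' @export
simple_main_effects <- function(fit, factor, alpha = 0.05) {
  stopifnot(inherits(fit, "anova_table"))
  other <- if (factor == fit$factor_a) fit$factor_b else fit$factor_a
  data <- stats::model.frame(fit$fit)
  y <- data[[fit$response]]
  fac <- data[[factor]]; byf <- data[[other]]
  a <- nlevels(fac)
  dfn <- a - 1L
  f_crit <- dfn * stats::qf(1 - alpha, dfn, fit$residual_df)
  out <- lapply(levels(byf), function(lv) {
    sel <- byf == lv
    if (sum(sel) < 2L || length(unique(fac[sel])) < 2L) {
      warning("level ", lv, " skipped: fewer than 2 observations per cell")
      return(NULL)
    }
    ys <- y[sel]; fs <- droplevels(fac[sel])
    cell_n <- tapply(ys, fs, length)
    cell_m <- tapply(ys, fs, mean)
    ss <- sum(cell_n * (cell_m - mean(ys))^2)
    fval <- (ss / dfn) / fit$residual_ms
    data.frame(level = lv, ss = ss, df = dfn, f = fval, f_crit = f_crit,
               significant = fval > f_crit,
               p = stats::pf(fval, dfn, fit$residual_df, lower.tail = FALSE))
  })
  do.call(rbind, out)
}

#' Exact fair-coin binomial mass
#'
#' `C(n, k) / 2^n` with an integer-arithmetic path (exact for all n <= 64 up
#' to double representability) and the "1 in N" rendering
#' `N = round(2^n / C(n, k))`: (20, 18) gives 190 / 1,048,576, i.e.
#' 1 in 5,519.
#'
#' @param n number of trials (<= 64).
#' @param k number of successes (0 <= k <= n).
#' @param tail if TRUE, return the upper-tail mass `P(X >= k)` instead of
#'   the exact-k mass.
#' @return list: `probability`, `one_in`, `numerator` (C(n,k) or tail sum),
#'   `denominator` (2^n).
#' @export
binomial_exact_mass <- function(n, k, tail = FALSE) {
  if (k < 0 || k > n) stop("k must lie in [0, n]")
  if (n > 64) stop("n must be <= 64")
  num <- if (tail) sum(choose(n, k:n)) else choose(n, k)
  den <- 2^n
  p <- num / den
  list(probability = p, one_in = round(den / num),
       numerator = num, denominator = den)
}
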