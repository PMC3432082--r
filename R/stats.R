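#' Per-group mean and SEM
#'
#' Group summaries in the convention the counting analyses report:
#' mean +/- standard error of the mean, one observation per experimental
#' unit (e.g. one projected field per fly).
#'
#' @param values Numeric observations.
#' @param groups Group labels (coerced to factor).
#' @return Data frame `group, n, mean, sem`; `sem` is `NA` for `n = 1`
#'   (sample s.d. uses the `n - 1` denominator).
#' @export
group_summary <- function(values, groups) {
  stopifnot(length(values) == length(groups), length(values) >= 1L,
            all(is.finite(values)))
  g <- factor(groups)
  if (any(table(g) == 0L)) stop("empty group", call. = FALSE)
  out <- do.call(rbind, lapply(levels(g), function(lv) {
    v <- values[g == lv]
    data.frame(group = lv, n = length(v), mean = mean(v),
               sem = if (length(v) > 1L) sd(v) / sqrt(length(v)) else NA_real_)
  }))
  rownames(out) <- NULL
  out
}

# Pooled within-group mean square and its df across all groups.
pooled_ms_within <- function(values, g) {
  n <- length(values)
  k <- nlevels(g)
  fit <- aov(values ~ g)
  ssw <- sum(residuals(fit)^2)
  list(ms = ssw / (n - k), df = n - k, ssw = ssw)
}

#' One-way fixed-effects ANOVA
#'
#' Standard sums of squares via [stats::aov()]; `F = MS_between /
#' MS_within` with p from the F distribution. With exactly two groups, F
#' equals the square of the pooled-variance two-sample t statistic.
#'
#' @param values Numeric observations.
#' @param groups Group labels (>= 2 levels; total n greater than the
#'   number of groups).
#' @return An `anova_result`: `F`, `df_between`, `df_within`, `p`,
#'   `alpha = 0.05`, and the aov fit.
#' @export
one_way_anova <- function(values, groups) {
  g <- factor(groups)
  stopifnot(length(values) == length(g), all(is.finite(values)))
  if (nlevels(g) < 2L) stop("at least 2 groups required", call. = FALSE)
  if (length(values) <= nlevels(g)) {
    stop("total n must exceed the number of groups", call. = FALSE)
  }
  ss_tot <- sum((values - mean(values))^2)
  if (ss_tot == 0) {
    stop("degenerate data: zero between- and within-group variance",
         call. = FALSE)
  }
  fit <- aov(values ~ g)
  s <- summary(fit)[[1]]
  ss <- s[["Sum Sq"]]
  df <- as.integer(s[["Df"]])
  ss[ss < 1e-12 * ss_tot] <- 0                 # QR round-off guard
  f <- if (ss[2] == 0) Inf else (ss[1] / df[1]) / (ss[2] / df[2])
  if (ss[1] == 0) f <- 0
  structure(list(F = f, df_between = df[1], df_within = df[2],
                 p = if (ss[1] == 0) 1 else
                   pf(f, df[1], df[2], lower.tail = FALSE),
                 alpha = 0.05, fit = fit),
            class = "anova_result")
}

#' @export
print.anova_result <- function(x, ...) {
  cat(sprintf("<anova_result> F(%d, %d) = %.4g, p = %.4g\n",
              x$df_between, x$df_within, x$F, x$p))
  invisible(x)
}

#' Two-way fixed-effects ANOVA
#'
#' Main effects and interaction. Balanced designs use the textbook
#' cell-mean sums of squares (sequential and type II coincide);
#' unbalanced designs use type II model-comparison sums of squares via
#' [car::Anova()], flagged in the output.
#'
#' @param values Numeric observations.
#' @param factor1,factor2 Factors with >= 2 levels each; every cell must
#'   contain at least one observation.
#' @return An `anova2_result`: data frame `table` with one row per term
#'   (`df`, `F`, `p`), `df_within`, `balanced`, `ss_type`.
#' @export
two_way_anova <- function(values, factor1, factor2) {
  a <- factor(factor1); b <- factor(factor2)
  stopifnot(length(values) == length(a), length(values) == length(b),
            all(is.finite(values)))
  if (nlevels(a) < 2L || nlevels(b) < 2L) {
    stop("both factors need at least 2 levels", call. = FALSE)
  }
  cells <- table(a, b)
  if (any(cells == 0L)) {
    stop("empty design cell(s): every factor combination needs data",
         call. = FALSE)
  }
  balanced <- length(unique(as.vector(cells))) == 1L
  ss_tot <- sum((values - mean(values))^2)
  if (balanced) {
    s <- summary(aov(values ~ a * b))[[1]]
    terms <- trimws(rownames(s))[1:3]
    ss <- s[["Sum Sq"]][1:4]
    df <- s[["Df"]][1:4]
    ss_term <- ss[1:3]; df_term <- df[1:3]
    ssw <- ss[4]; dfw <- df[4]
    ss_type <- "I (balanced)"
  } else {
    fit <- lm(values ~ a * b)
    s <- car::Anova(fit, type = 2)
    terms <- trimws(rownames(s))[1:3]
    ss_term <- s[["Sum Sq"]][1:3]; df_term <- s[["Df"]][1:3]
    ssw <- s[["Sum Sq"]][4]; dfw <- s[["Df"]][4]
    ss_type <- "II"
  }
  if (ss_tot == 0) {                           # constant response
    ss_term[] <- 0
    ssw <- 0
  } else {                                     # QR round-off guard
    tol <- 1e-12 * ss_tot
    ss_term[ss_term < tol] <- 0
    if (ssw < tol) ssw <- 0
  }
  msw <- if (dfw > 0) ssw / dfw else NA_real_
  f <- (ss_term / df_term) / msw
  f[ss_term == 0] <- 0
  if (ssw == 0) f[ss_term > 0] <- Inf
  p <- pf(f, df_term, dfw, lower.tail = FALSE)
  p[ss_term == 0] <- 1
  terms <- sub("^a$", "factor1", terms)
  terms <- sub("^b$", "factor2", terms)
  terms <- sub("^a:b$", "factor1:factor2", terms)
  structure(list(table = data.frame(term = terms, df = df_term,
                                    F = f, p = p),
                 df_within = dfw, balanced = balanced, ss_type = ss_type,
                 alpha = 0.05),
            class = "anova2_result")
}

#' @export
print.anova2_result <- function(x, ...) {
  cat(sprintf("<anova2_result> type %s sums of squares, df_within = %d\n",
              x$ss_type, x$df_within))
  print(x$table, row.names = FALSE)
  invisible(x)
}

#' Dunnett many-to-one post-test
#'
#' Compares every treatment group against a shared control with
#' family-wise error control. Statistics are
#' `t_i = (mean_i - mean_ctrl) / sqrt(MS_within (1/n_i + 1/n_ctrl))`;
#' adjusted p-values are two-sided exceedance probabilities of the
#' max-|t| statistic under a seeded Monte-Carlo simulation of the null
#' with the design's exact correlation structure (group means and a
#' shared pooled variance simulated directly), so arbitrary unbalanced
#' designs need no critical-value tables.
#'
#' @param values Numeric observations.
#' @param groups Group labels.
#' @param control Label of the control group.
#' @param alpha Family-wise significance level (default 0.05).
#' @param n_mc Monte-Carlo draws (default 200000).
#' @param seed Optional integer seed; identical seeds give identical
#'   adjusted p-values.
#' @return Data frame `comparison, estimate, statistic, adjusted_p,
#'   significant`, with attributes `df`, `ms_within`, `n_mc`.
#' @export
dunnett_posthoc <- function(values, groups, control, alpha = 0.05,
                            n_mc = 200000L, seed = NULL) {
  g <- factor(groups)
  stopifnot(length(values) == length(g), all(is.finite(values)))
  if (!control %in% levels(g)) {
    stop(sprintf("control group '%s' not found", control), call. = FALSE)
  }
  g <- relevel(g, ref = control)
  lev <- levels(g)
  if (length(lev) < 2L) stop("need at least one treatment group",
                             call. = FALSE)
  ns <- as.vector(table(g))
  means <- tapply(values, g, mean)
  pm <- pooled_ms_within(values, g)
  if (pm$df < 1L || pm$ms <= 0) {
    stop("pooled within-group variance unavailable", call. = FALSE)
  }
  est <- means[-1] - means[1]
  se <- sqrt(pm$ms * (1 / ns[-1] + 1 / ns[1]))
  t_obs <- est / se
  k <- length(lev) - 1L
  max_t <- with_seed(seed, {
    z <- matrix(rnorm(n_mc * length(lev)), n_mc, length(lev))
    z <- sweep(z, 2L, sqrt(ns), `/`)             # simulated group means
    v <- rchisq(n_mc, pm$df) / pm$df             # pooled variance ratio
    tmat <- (z[, -1, drop = FALSE] - z[, 1]) /
      outer(sqrt(v), sqrt(1 / ns[-1] + 1 / ns[1]))
    apply(abs(tmat), 1L, max)
  })
  adj_p <- vapply(abs(t_obs), function(t) mean(max_t >= t), numeric(1))
  out <- data.frame(comparison = paste(lev[-1], "-", lev[1]),
                    estimate = as.vector(est),
                    statistic = as.vector(t_obs),
                    adjusted_p = adj_p,
                    significant = adj_p < alpha)
  rownames(out) <- NULL
  attr(out, "df") <- pm$df
  attr(out, "ms_within") <- pm$ms
  attr(out, "n_mc") <- n_mc
  out
}

#' Bonferroni-corrected pairwise comparisons
#'
#' Two-sample t tests on the pooled within-group mean square (all groups),
#' with `adjusted_p = min(1, m * p_raw)` over the `m` requested
#' comparisons.
#'
#' @param values Numeric observations.
#' @param groups Group labels.
#' @param comparisons List of length-2 character vectors naming group
#'   pairs; `NULL` (default) tests all pairs.
#' @param alpha Significance level (default 0.05).
#' @return Data frame `comparison, estimate, statistic, p_raw, adjusted_p,
#'   significant`.
#' @export
bonferroni_pairwise <- function(values, groups, comparisons = NULL,
                                alpha = 0.05) {
  g <- factor(groups)
  stopifnot(length(values) == length(g), all(is.finite(values)))
  lev <- levels(g)
  if (is.null(comparisons)) {
    cmb <- utils::combn(lev, 2L)
    comparisons <- lapply(seq_len(ncol(cmb)), function(i) cmb[, i])
  }
  for (cp in comparisons) {
    if (length(cp) != 2L || !all(cp %in% lev)) {
      stop(sprintf("unknown group(s) in comparison: %s",
                   paste(cp, collapse = " vs ")), call. = FALSE)
    }
  }
  ns <- as.vector(table(g))
  names(ns) <- lev
  means <- tapply(values, g, mean)
  pm <- pooled_ms_within(values, g)
  m <- length(comparisons)
  rows <- lapply(comparisons, function(cp) {
    est <- means[cp[1]] - means[cp[2]]
    se <- sqrt(pm$ms * (1 / ns[cp[1]] + 1 / ns[cp[2]]))
    t <- est / se
    p_raw <- 2 * pt(-abs(t), pm$df)
    data.frame(comparison = paste(cp[1], "-", cp[2]),
               estimate = as.vector(est), statistic = as.vector(t),
               p_raw = as.vector(p_raw),
               adjusted_p = min(1, m * p_raw))
  })
  out <- do.call(rbind, rows)
  out$significant <- out$adjusted_p < alpha
  rownames(out) <- NULL
  attr(out, "df") <- pm$df
  attr(out, "ms_within") <- pm$ms
  out
}
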