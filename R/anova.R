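#' One-way ANOVA decomposition
#'
#' Standard one-way sums-of-squares decomposition, returning the components
#' the percent-explained-variance effect sizes are built from.
#'
#' @param values Numeric observations.
#' @param labels Group labels (coerced to factor), same length as `values`.
#' @return An object of class `anova_result`: `ssq_effect`, `ssq_total`,
#'   `ms_error`, `df_effect`, `df_error`, `f_stat`, `n_obs`, `p_value`.
#' @examples
#' a <- one_way_anova(c(1, 2, 3, 4, 5, 6), rep(c("a", "b"), each = 3))
#' a$f_stat  # 13.5 on df (1, 4)
#' @export
one_way_anova <- function(values, labels) {
  labels <- factor(labels)
  labels <- droplevels(labels)
  if (nlevels(labels) < 2)
    stop("invalid-input: need >= 2 non-empty groups", call. = FALSE)
  if (length(values) != length(labels))
    stop("invalid-input: values and labels differ in length", call. = FALSE)
  if (any(table(labels) == 0))
    stop("invalid-input: empty group", call. = FALSE)
  n <- length(values)
  k <- nlevels(labels)
  gm <- tapply(values, labels, mean)
  gn <- tabulate(labels)
  mu <- mean(values)
  ssb <- sum(gn * (gm - mu)^2)
  sst <- sum((values - mu)^2)
  ssw <- max(sst - ssb, 0)
  df_e <- k - 1L
  df_err <- n - k
  ms_err <- if (df_err > 0) ssw / df_err else NA_real_
  f <- if (isTRUE(ms_err > 0)) (ssb / df_e) / ms_err
       else if (ssb > 0) Inf else 0
  p <- if (is.finite(f)) stats::pf(f, df_e, df_err, lower.tail = FALSE)
       else if (is.infinite(f)) 0 else 1
  structure(list(ssq_effect = ssb, ssq_total = sst, ms_error = ms_err,
                 df_effect = df_e, df_error = df_err, f_stat = f,
                 n_obs = n, p_value = p),
            class = "anova_result")
}

#' Omega-squared effect size (percent explained variance)
#'
#' `omega^2 = (SSQ_e - df_e * MS_err) / (SSQ_total + MS_err)`. The value can
#' be negative when the effect mean square falls below the error mean
#' square; negative values are reported as-is and must never be clamped
#' before statistics (clamping exists only in [display_log_transform()]).
#'
#' @param a An `anova_result` from [one_way_anova()].
#' @return Numeric effect size, interpretable as the fraction of variance
#'   explained by the grouping factor.
#' @export
omega_squared <- function(a) {
  stopifnot(inherits(a, "anova_result"))
  den <- a$ssq_total + a$ms_error
  if (!is.finite(den) || den == 0)
    stop("undefined-value: ssq_total + ms_error is zero", call. = FALSE)
  (a$ssq_effect - a$df_effect * a$ms_error) / den
}

#' Partial omega-squared from F statistic, df and observation count
#'
#' `omega_p^2 = df_e * (F - 1) / (df_e * (F - 1) + n)`. On a one-way design
#' this is numerically identical to [omega_squared()]; it is the form used
#' when only the F statistic, its effect degrees of freedom and the number
#' of observations are available.
#'
#' @param f_stat F statistic of the effect.
#' @param df_effect Effect degrees of freedom (groups - 1).
#' @param n_obs Total number of observations.
#' @return Numeric effect size.
#' @examples
#' partial_omega_squared(89.64, 3, 428)  # 0.3832
#' @export
partial_omega_squared <- function(f_stat, df_effect, n_obs) {
  if (any(n_obs <= 0)) stop("invalid-input: n_obs must be > 0", call. = FALSE)
  if (any(df_effect < 1))
    stop("invalid-input: df_effect must be >= 1", call. = FALSE)
  df_effect * (f_stat - 1) / (df_effect * (f_stat - 1) + n_obs)
}

# Vectorized one-way decomposition over the rows of X (rows x trials),
# sharing one label vector. Returns per-row omega^2, F and p. This is the
# permutation-loop workhorse: one BLAS matrix product per call.
anova_rows <- function(X, labels) {
  labels <- droplevels(factor(labels))
  k <- nlevels(labels)
  n <- length(labels)
  stopifnot(k >= 2, ncol(X) == n)
  G <- stats::model.matrix(~ labels - 1)
  gn <- tabulate(labels)
  S <- X %*% G                       # rows x k group sums
  tot <- rowSums(S)
  ssb <- rowSums(sweep(S^2, 2, gn, `/`)) - tot^2 / n
  sst <- rowSums(X^2) - tot^2 / n
  ssw <- pmax(sst - ssb, 0)
  df_e <- k - 1L
  df_err <- n - k
  ms_err <- ssw / df_err
  den <- sst + ms_err
  pev <- ifelse(den > 0, (ssb - df_e * ms_err) / den, NA_real_)
  f <- ifelse(ms_err > 0, (ssb / df_e) / ms_err, ifelse(ssb > 0, Inf, 0))
  p <- ifelse(is.finite(f), stats::pf(f, df_e, df_err, lower.tail = FALSE),
              ifelse(is.infinite(f), 0, 1))
  list(pev = pev, f = f, p = p, df_effect = df_e, df_error = df_err, n = n)
}
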