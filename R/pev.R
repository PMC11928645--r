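#' Per-unit PEV time course
#'
#' Computes, for every unit and time bin, the omega-squared effect size of a
#' one-way ANOVA of firing rate on `labels` — the percent explained
#' variance (PEV) time course. Optionally attaches a permutation null band
#' and per-bin significance flags (observed PEV exceeding 95% of
#' label-shuffled values).
#'
#' @param rates A `rate_tensor` from [bin_firing_rates()].
#' @param labels Per-trial group labels aligned with the tensor's trials.
#' @param n_perm If > 0, number of label permutations for the null band.
#' @param quantiles Null-band quantiles (the plotted band).
#' @param seed Seed for the permutations.
#' @return A `pev_series`: list with `pev` (units x bins matrix), `centers`,
#'   `unit_ids`, and when permuted also `band_lo`, `band_hi`, `upper95`,
#'   `significant`.
#' @export
pev_timecourse <- function(rates, labels, n_perm = 0L,
                           quantiles = c(0.025, 0.975), seed = 1L) {
  stopifnot(inherits(rates, "rate_tensor"))
  d <- dim(rates)
  if (length(labels) != d[2])
    stop("invalid-input: labels must align with trials", call. = FALSE)
  X <- flatten_bins(rates)
  res <- anova_rows(X, labels)
  pev <- matrix(res$pev, d[1], d[3])
  rownames(pev) <- attr(rates, "unit_ids")
  out <- structure(list(pev = pev, unit_ids = attr(rates, "unit_ids"),
                        centers = attr(rates, "grid")$centers,
                        grid = attr(rates, "grid"), n_perm = 0L),
                   class = "pev_series")
  if (n_perm > 0) {
    nb <- permutation_band(rates, labels, n_perm = n_perm,
                           quantiles = quantiles, seed = seed)
    out$band_lo <- nb$lo
    out$band_hi <- nb$hi
    out$upper95 <- nb$upper95
    out$significant <- pev > nb$upper95
    out$n_perm <- nb$n_perm
  }
  out
}

# rows = unit x bin (unit index fastest), columns = trials
flatten_bins <- function(rates) {
  d <- dim(rates)
  matrix(aperm(unclass(rates), c(1, 3, 2)), d[1] * d[3], d[2])
}

#' Permutation null band for PEV time courses
#'
#' Shuffles the trial labels `n_perm` times, recomputes the PEV of every
#' unit and bin under each shuffle, and returns empirical per-unit-per-bin
#' quantiles. Significance uses the upper-tail criterion (observed value
#' exceeding 95% of shuffled values); the `[2.5, 97.5]` band is what plots
#' display.
#'
#' @inheritParams pev_timecourse
#' @param n_perm Number of permutations (>= 100).
#' @return List with matrices `lo`, `hi` (the requested quantiles),
#'   `upper95` (the 0.95 quantile used for the significance flag), plus
#'   `n_perm` and `quantiles`.
#' @export
permutation_band <- function(rates, labels, n_perm = 1000L,
                             quantiles = c(0.025, 0.975), seed = 1L) {
  stopifnot(inherits(rates, "rate_tensor"))
  if (n_perm < 100) stop("invalid-input: n_perm must be >= 100", call. = FALSE)
  labels <- factor(labels)
  if (nlevels(droplevels(labels)) < 2)
    stop("invalid-input: labels are constant", call. = FALSE)
  d <- dim(rates)
  X <- flatten_bins(rates)
  null <- with_seed(seed, {
    vapply(seq_len(n_perm), function(i)
      anova_rows(X, labels[sample.int(d[2])])$pev,
      numeric(nrow(X)))
  })
  qs <- t(apply(null, 1, stats::quantile,
                probs = c(quantiles, 0.95), na.rm = TRUE, names = FALSE))
  list(lo = matrix(qs[, 1], d[1], d[3]), hi = matrix(qs[, 2], d[1], d[3]),
       upper95 = matrix(qs[, 3], d[1], d[3]), n_perm = as.integer(n_perm),
       quantiles = quantiles)
}

#' Population summary of PEV series
#'
#' Mean and standard error of PEV across units per bin, and the percentage
#' of units flagged significant per bin (when the series carries
#' permutation flags). SEM across units is used because the population
#' pools all recorded units.
#'
#' @param series A `pev_series`.
#' @return Data frame with `bin_center_s`, `mean_pev`, `sem_pev`,
#'   `pct_significant`, and attribute `sem_defined` (FALSE for a single
#'   unit, where SEM is reported as 0).
#' @export
population_summary <- function(series) {
  stopifnot(inherits(series, "pev_series"))
  p <- series$pev
  if (nrow(p) < 1) stop("invalid-input: no units", call. = FALSE)
  nu <- nrow(p)
  m <- colMeans(p, na.rm = TRUE)
  s <- if (nu > 1) apply(p, 2, stats::sd, na.rm = TRUE) / sqrt(nu)
       else rep(0, ncol(p))
  pct <- if (!is.null(series$significant))
    100 * colMeans(series$significant, na.rm = TRUE) else rep(NA_real_, ncol(p))
  out <- data.frame(bin_center_s = series$centers, mean_pev = m, sem_pev = s,
                    pct_significant = pct)
  attr(out, "sem_defined") <- nu > 1
  out
}

#' Classify units by significant factors
#'
#' A unit is significant for a factor when any tested non-overlapping bin's
#' one-way ANOVA p-value survives Bonferroni correction across all
#' (bin x factor) tests performed for that unit. Units are partitioned into
#' location-only, color-only, both, and none.
#'
#' @param rates A `rate_tensor` (pre-cue trials).
#' @param location_labels Per-trial cue-location labels.
#' @param color_labels Per-trial color labels (session color index at the
#'   tested location).
#' @param alpha Family-wise significance level.
#' @param bins Bin indices to test; defaults to non-overlapping bins.
#' @return List with `class` (per-unit factor), `counts`, and the per-unit
#'   minimum Bonferroni-adjusted p per factor.
#' @export
classify_units <- function(rates, location_labels, color_labels,
                           alpha = 0.05, bins = NULL) {
  stopifnot(inherits(rates, "rate_tensor"))
  if (is.null(bins)) bins <- select_nonoverlapping(attr(rates, "grid"))
  d <- dim(rates)
  sub <- unclass(rates)[, , bins, drop = FALSE]
  X <- matrix(aperm(sub, c(1, 3, 2)), d[1] * length(bins), d[2])
  p_loc <- matrix(anova_rows(X, location_labels)$p, d[1], length(bins))
  p_col <- matrix(anova_rows(X, color_labels)$p, d[1], length(bins))
  m <- 2 * length(bins)                 # Bonferroni family: bins x 2 factors
  sig_loc <- apply(p_loc, 1, function(p) any(p < alpha / m))
  sig_col <- apply(p_col, 1, function(p) any(p < alpha / m))
  cls <- ifelse(sig_loc & sig_col, "both",
         ifelse(sig_loc, "location_only",
         ifelse(sig_col, "color_only", "none")))
  cls <- factor(cls, levels = c("location_only", "color_only", "both", "none"))
  names(cls) <- attr(rates, "unit_ids")
  list(class = cls, counts = table(cls),
       p_location = pmin(apply(p_loc, 1, min) * m, 1),
       p_color = pmin(apply(p_col, 1, min) * m, 1))
}

#' Attentional shift (delta PEV) table
#'
#' Gain is the color PEV in pre-cue trials minus no-cue trials at the same
#' location and bin; loss is pre-cue minus cue-other (cue at a different
#' location). The overall shift per unit and bin is `(gain + loss) / 2`;
#' population figures report the absolute value of the across-unit mean.
#' All inputs must share the same non-overlapping bin grid.
#'
#' @param pev_precue,pev_nocue,pev_cueother Units x bins PEV matrices for
#'   the three condition sets.
#' @param centers Optional bin centers (seconds) for labeling.
#' @return A `shift_table`: list with matrices `gain`, `loss`, `overall`.
#' @export
attentional_shift <- function(pev_precue, pev_nocue, pev_cueother,
                              centers = NULL) {
  dm <- dim(pev_precue)
  if (!identical(dm, dim(pev_nocue)) || !identical(dm, dim(pev_cueother)))
    stop("invalid-input: PEV matrices must share dimensions (same units, ",
         "same non-overlapping bin grid)", call. = FALSE)
  gain <- pev_precue - pev_nocue
  loss <- pev_precue - pev_cueother
  structure(list(gain = gain, loss = loss, overall = (gain + loss) / 2,
                 centers = centers),
            class = "shift_table")
}

#' @export
print.shift_table <- function(x, ...) {
  cat(sprintf("Attentional shift table: %d units x %d bins\n",
              nrow(x$gain), ncol(x$gain)))
  cat(sprintf("  mean gain %.4f | mean loss %.4f | |mean overall| %.4f\n",
              mean(x$gain, na.rm = TRUE), mean(x$loss, na.rm = TRUE),
              abs(mean(x$overall, na.rm = TRUE))))
  invisible(x)
}

#' Per-bin one-sample sign-rank tests with Bonferroni correction
#'
#' Wilcoxon signed-rank test of the per-unit shift values against zero,
#' one bin at a time, Bonferroni-corrected across the tested bins.
#'
#' @param shift_values Units x bins matrix (e.g. `gain` from
#'   [attentional_shift()]).
#' @param n_bins_tested Bonferroni family size; defaults to the number of
#'   columns.
#' @param alpha Family-wise level.
#' @param alternative Test direction (default two-sided).
#' @return Data frame with per-bin raw and adjusted p, significance flag,
#'   and a degenerate flag for all-zero bins (p = 1 by convention).
#' @export
signrank_bonferroni <- function(shift_values, n_bins_tested = ncol(shift_values),
                                alpha = 0.05, alternative = "two.sided") {
  if (nrow(shift_values) < 6)
    warning("fewer than 6 units: sign-rank cannot reach significance")
  p_raw <- apply(shift_values, 2, function(v) {
    v <- v[is.finite(v)]
    if (length(v) == 0 || all(v == 0)) return(NA_real_)
    stats::wilcox.test(v, mu = 0, alternative = alternative,
                       exact = FALSE, correct = TRUE)$p.value
  })
  degenerate <- is.na(p_raw)
  p_raw[degenerate] <- 1
  p_adj <- pmin(p_raw * n_bins_tested, 1)
  data.frame(bin = seq_along(p_raw), p_raw = p_raw, p_adj = p_adj,
             significant = p_adj < alpha, degenerate = degenerate)
}

#' Sign-preserving decadic log transform for display
#'
#' For plotting PEV values across orders of magnitude: the sign is kept
#' separately and the magnitude is clamped below at `floor` before taking
#' log10 (so -0.001 maps to sign -1, magnitude -3). Statistics are always
#' computed on original values; this transform is display-only.
#'
#' @param values Numeric vector.
#' @param floor Magnitude floor (default 1e-6); zero maps to the floor with
#'   positive sign by convention.
#' @return List with `sign` (+1/-1) and `log10_magnitude`.
#' @export
display_log_transform <- function(values, floor = 1e-6) {
  sgn <- ifelse(values < 0, -1, 1)
  list(sign = sgn, log10_magnitude = log10(pmax(abs(values), floor)))
}

#' @export
print.pev_series <- function(x, ...) {
  cat(sprintf("PEV series: %d units x %d bins", nrow(x$pev), ncol(x$pev)))
  if (x$n_perm > 0)
    cat(sprintf(" (permutation band, %d shuffles)", x$n_perm))
  cat("\n  population mean PEV range: [",
      sprintf("%.4f", min(colMeans(x$pev, na.rm = TRUE))), ", ",
      sprintf("%.4f", max(colMeans(x$pev, na.rm = TRUE))), "]\n", sep = "")
  invisible(x)
}

#' @export
plot.pev_series <- function(x, ...) {
  s <- population_summary(x)
  graphics::plot(s$bin_center_s, s$mean_pev, type = "l", lwd = 2,
                 xlab = "time (s)", ylab = "mean PEV (omega^2)", ...)
  graphics::polygon(c(s$bin_center_s, rev(s$bin_center_s)),
                    c(s$mean_pev - s$sem_pev, rev(s$mean_pev + s$sem_pev)),
                    col = grDevices::adjustcolor("black", 0.2), border = NA)
  invisible(x)
}
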