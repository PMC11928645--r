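#' Assemble a pseudo-simultaneous population trial set
#'
#' Units were recorded in different sessions; pseudo-simultaneous trials
#' combine them as if simultaneous by drawing, independently for every
#' unit, one real trial of the matching condition per pseudo-trial. The
#' default (40 pseudo-trials per condition, three conditions) gives the
#' 120-trial set the decoder resamples from.
#'
#' @param rates A `rate_tensor`.
#' @param labels Per-trial condition labels (e.g. cue location).
#' @param n_per_condition Pseudo-trials per condition.
#' @param seed Integer seed.
#' @param replace Draw real trials with replacement (required when a unit
#'   has fewer real trials than pseudo-trials; the default). With
#'   `replace = FALSE`, insufficient trials raise an error.
#' @return A `pseudo_trial_set`: list with `x` (pseudo-trials x units x
#'   bins array), `labels`, `centers`, `n_per_condition`.
#' @export
build_pseudo_trials <- function(rates, labels, n_per_condition = 40L,
                                seed = 1L, replace = TRUE) {
  stopifnot(inherits(rates, "rate_tensor"))
  d <- dim(rates)
  labels <- droplevels(factor(labels))
  if (length(labels) != d[2])
    stop("invalid-input: labels must align with trials", call. = FALSE)
  conds <- levels(labels)
  n_rows <- n_per_condition * length(conds)
  x <- array(0, dim = c(n_rows, d[1], d[3]))
  out_lab <- factor(rep(conds, each = n_per_condition), levels = conds)
  with_seed(seed, {
    for (ci in seq_along(conds)) {
      pool <- which(labels == conds[ci])
      if (!replace && length(pool) < n_per_condition)
        stop("insufficient trials for condition '", conds[ci],
             "' without replacement (", length(pool), " < ",
             n_per_condition, ")", call. = FALSE)
      rows <- (ci - 1L) * n_per_condition + seq_len(n_per_condition)
      for (u in seq_len(d[1])) {
        draw <- if (replace) pool[sample.int(length(pool), n_per_condition,
                                             replace = TRUE)]
                else pool[sample.int(length(pool), n_per_condition)]
        x[rows, u, ] <- unclass(rates)[u, draw, ]
      }
    }
  })
  structure(list(x = x, labels = out_lab,
                 centers = attr(rates, "grid")$centers,
                 grid = attr(rates, "grid"),
                 unit_ids = attr(rates, "unit_ids"),
                 n_per_condition = as.integer(n_per_condition),
                 zscored = FALSE),
            class = "pseudo_trial_set")
}

#' Z-score a pseudo-trial set per bin
#'
#' Default normalization pools the mean and standard deviation over all
#' units and pseudo-trials within each bin (population-level
#' normalization); `per_unit = TRUE` normalizes each unit separately
#' within each bin instead. Bins (or unit-bins) with degenerate variance
#' are set to 0 and flagged.
#'
#' @param pseudo A `pseudo_trial_set`.
#' @param per_unit Use per-unit rather than pooled normalization.
#' @return The transformed `pseudo_trial_set` with a `degenerate` attribute.
#' @export
zscore_per_bin <- function(pseudo, per_unit = FALSE) {
  stopifnot(inherits(pseudo, "pseudo_trial_set"))
  x <- pseudo$x
  nb <- dim(x)[3]
  if (per_unit) {
    degenerate <- matrix(FALSE, dim(x)[2], nb)
    for (b in seq_len(nb)) {
      m <- colMeans(x[, , b, drop = FALSE][, , 1])
      s <- apply(x[, , b, drop = FALSE][, , 1], 2, stats::sd)
      bad <- !is.finite(s) | s < 1e-12
      s[bad] <- 1
      x[, , b] <- sweep(sweep(x[, , b, drop = FALSE][, , 1], 2, m), 2, s, `/`)
      x[, bad, b] <- 0
      degenerate[, b] <- bad
    }
  } else {
    degenerate <- logical(nb)
    for (b in seq_len(nb)) {
      sl <- x[, , b]
      m <- mean(sl); s <- stats::sd(as.vector(sl))
      if (!is.finite(s) || s < 1e-12) {
        x[, , b] <- 0
        degenerate[b] <- TRUE
      } else x[, , b] <- (sl - m) / s
    }
  }
  pseudo$x <- x
  pseudo$zscored <- TRUE
  pseudo$degenerate <- degenerate
  pseudo
}

# Linear multi-class max-margin classifier (one-vs-one reduction).
fit_maxmargin <- function(x, y) {
  e1071::svm(x = x, y = factor(y), kernel = "linear", scale = FALSE, cost = 1)
}

# stratified train/test split indices by condition
stratified_split <- function(labels, train_frac) {
  train <- integer(0)
  for (l in levels(labels)) {
    idx <- which(labels == l)
    n_tr <- floor(length(idx) * train_frac)
    train <- c(train, idx[sample.int(length(idx), n_tr)])
  }
  list(train = sort(train), test = setdiff(seq_along(labels), train))
}

#' Cross-temporal decoding of condition labels
#'
#' For each resample, draws a stratified 90/10 train/test split of the
#' pseudo-trials, fits a linear max-margin classifier on each training bin,
#' and tests it on every bin (temporal generalization). Performance per
#' (train bin, test bin) cell is the fraction of held-out pseudo-trials
#' classified correctly, averaged over resamples.
#'
#' @param pseudo A z-scored `pseudo_trial_set` with >= 2 conditions.
#' @param train_frac Fraction of pseudo-trials (per condition) used for
#'   training.
#' @param n_resamples Number of random splits.
#' @param seed Integer seed.
#' @param bins Bin indices to use (default: all bins in the set).
#' @param shuffle Shuffle labels independently per resample (used by
#'   [shuffled_baseline()]).
#' @param diagonal_only Skip off-diagonal (train != test) cells.
#' @return A `decoding_matrix`: `performance` (train x test mean),
#'   `spread` (per-cell SD), `resamples` (train x test x resample array),
#'   `centers`, `chance`, and classifier metadata.
#' @export
decode_cross_temporal <- function(pseudo, train_frac = 0.9,
                                  n_resamples = 1000L, seed = 1L,
                                  bins = NULL, shuffle = FALSE,
                                  diagonal_only = FALSE) {
  stopifnot(inherits(pseudo, "pseudo_trial_set"))
  labels <- droplevels(pseudo$labels)
  if (nlevels(labels) < 2)
    stop("invalid-input: need >= 2 conditions to decode", call. = FALSE)
  if (is.null(bins)) bins <- seq_len(dim(pseudo$x)[3])
  n_test_per <- round(pseudo$n_per_condition * (1 - train_frac))
  if (n_test_per < 1)
    stop("invalid-config: train_frac leaves < 1 test trial per condition",
         call. = FALSE)
  nb <- length(bins)
  perf <- array(NA_real_, dim = c(nb, nb, n_resamples))
  with_seed(seed, {
    for (r in seq_len(n_resamples)) {
      lab_r <- if (shuffle) labels[sample.int(length(labels))] else labels
      sp <- stratified_split(lab_r, train_frac)
      y_tr <- lab_r[sp$train]; y_te <- lab_r[sp$test]
      for (bi in seq_len(nb)) {
        fit <- fit_maxmargin(pseudo$x[sp$train, , bins[bi]], y_tr)
        test_bins <- if (diagonal_only) bi else seq_len(nb)
        for (bj in test_bins) {
          pred <- stats::predict(fit, pseudo$x[sp$test, , bins[bj],
                                               drop = FALSE][, , 1])
          perf[bi, bj, r] <- mean(pred == y_te)
        }
      }
    }
  })
  structure(list(performance = apply(perf, c(1, 2), mean),
                 spread = apply(perf, c(1, 2), stats::sd),
                 resamples = perf, bins = bins,
                 centers = pseudo$centers[bins],
                 chance = 1 / nlevels(labels),
                 n_resamples = as.integer(n_resamples),
                 train_frac = train_frac, shuffled = shuffle,
                 classifier = "linear SVM (one-vs-one)",
                 null_lo = NULL, null_hi = NULL, significant = NULL,
                 clusters = NULL),
            class = "decoding_matrix")
}

#' Shuffled-label baseline for the decoder
#'
#' Repeats the full decoding procedure with condition labels permuted
#' independently on every resample, yielding the null distribution of
#' classification performance per cell (centered on the theoretical chance
#' level of 1/3 for three conditions).
#'
#' @inheritParams decode_cross_temporal
#' @return A `decoding_matrix` whose resample distribution is the null.
#' @export
shuffled_baseline <- function(pseudo, n_resamples = 1000L, seed = 1L,
                              train_frac = 0.9, bins = NULL,
                              diagonal_only = FALSE) {
  decode_cross_temporal(pseudo, train_frac = train_frac,
                        n_resamples = n_resamples, seed = seed, bins = bins,
                        shuffle = TRUE, diagonal_only = diagonal_only)
}

# 4-connected components of a logical matrix via BFS flood fill.
label_clusters <- function(mask) {
  lab <- matrix(0L, nrow(mask), ncol(mask))
  cur <- 0L
  for (i in seq_len(nrow(mask))) for (j in seq_len(ncol(mask))) {
    if (mask[i, j] && lab[i, j] == 0L) {
      cur <- cur + 1L
      queue <- list(c(i, j))
      lab[i, j] <- cur
      while (length(queue) > 0) {
        p <- queue[[1]]; queue <- queue[-1]
        for (d in list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))) {
          q <- p + d
          if (q[1] >= 1 && q[1] <= nrow(mask) && q[2] >= 1 &&
              q[2] <= ncol(mask) && mask[q[1], q[2]] && lab[q[1], q[2]] == 0L) {
            lab[q[1], q[2]] <- cur
            queue[[length(queue) + 1]] <- q
          }
        }
      }
    }
  }
  lab
}

#' Flag significant decoding cells and clusters
#'
#' Diagonal cells (train bin == test bin) are significant when the inner
#' 95% interval of the observed resample distribution lies wholly above
#' the null's inner 95% interval (a conservative criterion, at least
#' p < 0.025). Off-diagonal cells are first flagged at the 5% level
#' (observed mean above the null's 0.95 quantile), then only 4-connected
#' clusters larger than `min_cluster_bins` cells are retained.
#'
#' @param dm A `decoding_matrix` from [decode_cross_temporal()].
#' @param null A `decoding_matrix` from [shuffled_baseline()] on the same
#'   bins.
#' @param min_cluster_bins Minimum cluster size (clusters must *exceed*
#'   this many neighboring bins to survive).
#' @return The `decoding_matrix` with `significant`, `diag_significant`,
#'   `clusters` (list of cell index sets with sizes), and per-cell null
#'   quantiles filled in.
#' @export
significance_map <- function(dm, null, min_cluster_bins = 5L) {
  stopifnot(inherits(dm, "decoding_matrix"),
            inherits(null, "decoding_matrix"))
  if (!identical(dm$bins, null$bins))
    stop("invalid-input: observed and null matrices use different bins",
         call. = FALSE)
  q <- function(a, p) apply(a, c(1, 2), stats::quantile, probs = p,
                            na.rm = TRUE)
  null_hi975 <- q(null$resamples, 0.975)
  null_hi95 <- q(null$resamples, 0.95)
  null_lo <- q(null$resamples, 0.025)
  obs_lo <- q(dm$resamples, 0.025)
  nb <- nrow(dm$performance)
  diag_sig <- diag(obs_lo) > diag(null_hi975)
  flag <- dm$performance > null_hi95
  flag[is.na(flag)] <- FALSE
  lab <- label_clusters(flag)
  clusters <- list()
  if (max(lab) > 0) {
    for (cl in seq_len(max(lab))) {
      cells <- which(lab == cl, arr.ind = TRUE)
      if (nrow(cells) > min_cluster_bins)
        clusters[[length(clusters) + 1]] <- list(cells = cells,
                                                 size = nrow(cells))
    }
  }
  keep <- matrix(FALSE, nb, nb)
  for (cl in clusters) keep[cl$cells] <- TRUE
  dm$significant <- keep
  dm$diag_significant <- diag_sig
  dm$clusters <- clusters
  dm$null_lo <- null_lo
  dm$null_hi <- null_hi975
  dm$min_cluster_bins <- as.integer(min_cluster_bins)
  dm
}

#' Cross-trial-type transfer classification
#'
#' Fits the classifier on labeled pre-cue pseudo-trials and applies it,
#' bin by bin (same time bin for training and testing), to unlabeled
#' no-cue pseudo-trials. Reports the fraction of no-cue trials classified
#' into each location per bin, a chi-squared goodness-of-fit test against
#' the uniform expectation N/3 per location (Bonferroni-corrected across
#' bins), and the unweighted average fractions across bins.
#'
#' @param train_pseudo Labeled (pre-cue) `pseudo_trial_set`.
#' @param test_pseudo Unlabeled (no-cue) `pseudo_trial_set` over the same
#'   units and bins.
#' @param n_resamples Training subsets drawn per bin.
#' @param train_frac Fraction of training pseudo-trials used per resample.
#' @param seed Integer seed.
#' @param bins Bin indices (default all).
#' @param alpha Family-wise level for the chi-squared tests.
#' @return A `transfer_result`: per-bin data frame of class fractions,
#'   chi-squared statistic, df, adjusted p and significance, plus
#'   `overall` average fractions.
#' @export
transfer_decode <- function(train_pseudo, test_pseudo, n_resamples = 100L,
                            train_frac = 0.9, seed = 1L, bins = NULL,
                            alpha = 0.05) {
  stopifnot(inherits(train_pseudo, "pseudo_trial_set"),
            inherits(test_pseudo, "pseudo_trial_set"))
  if (dim(train_pseudo$x)[2] != dim(test_pseudo$x)[2])
    stop("invalid-input: train and test sets have different units",
         call. = FALSE)
  if (dim(train_pseudo$x)[3] != dim(test_pseudo$x)[3])
    stop("invalid-input: train and test sets have different bins",
         call. = FALSE)
  labels <- droplevels(train_pseudo$labels)
  if (is.null(bins)) bins <- seq_len(dim(train_pseudo$x)[3])
  classes <- levels(labels)
  nb <- length(bins)
  n_test <- dim(test_pseudo$x)[1]
  frac <- matrix(0, nb, length(classes), dimnames = list(NULL, classes))
  with_seed(seed, {
    for (bi in seq_len(nb)) {
      acc <- numeric(length(classes))
      for (r in seq_len(n_resamples)) {
        sp <- stratified_split(labels, train_frac)
        fit <- fit_maxmargin(train_pseudo$x[sp$train, , bins[bi]],
                             labels[sp$train])
        pred <- stats::predict(fit, test_pseudo$x[, , bins[bi],
                                                  drop = FALSE][, , 1])
        acc <- acc + as.numeric(table(factor(pred, levels = classes))) / n_test
      }
      frac[bi, ] <- acc / n_resamples
    }
  })
  expected <- n_test / length(classes)
  chi2 <- rowSums((frac * n_test - expected)^2 / expected)
  df <- length(classes) - 1L
  p_raw <- stats::pchisq(chi2, df, lower.tail = FALSE)
  p_adj <- pmin(p_raw * nb, 1)
  per_bin <- data.frame(bin_center_s = train_pseudo$centers[bins], frac,
                        chi2 = chi2, df = df, n = n_test, p_raw = p_raw,
                        p_adj = p_adj, significant = p_adj < alpha,
                        check.names = FALSE)
  structure(list(per_bin = per_bin, overall = colMeans(frac),
                 classes = classes, n_test = n_test,
                 n_resamples = as.integer(n_resamples)),
            class = "transfer_result")
}

#' @export
print.decoding_matrix <- function(x, ...) {
  cat(sprintf("Decoding matrix: %d x %d bins, %d resamples%s\n",
              nrow(x$performance), ncol(x$performance), x$n_resamples,
              if (isTRUE(x$shuffled)) " (shuffled-label null)" else ""))
  cat(sprintf("  diagonal performance: mean %.3f, max %.3f (chance %.3f)\n",
              mean(diag(x$performance), na.rm = TRUE),
              max(diag(x$performance), na.rm = TRUE), x$chance))
  if (!is.null(x$clusters))
    cat(sprintf("  %d significant cluster(s)\n", length(x$clusters)))
  invisible(x)
}

#' @export
plot.decoding_matrix <- function(x, ...) {
  graphics::image(x$centers, x$centers, t(x$performance),
                  xlab = "test bin (s)", ylab = "train bin (s)",
                  main = "cross-temporal decoding", ...)
  if (!is.null(x$significant) && any(x$significant))
    graphics::contour(x$centers, x$centers, t(x$significant * 1),
                      levels = 0.5, add = TRUE, drawlabels = FALSE)
  invisible(x)
}

#' @export
print.transfer_result <- function(x, ...) {
  cat("Transfer classification of no-cue trials (pre-cue-trained):\n")
  cat("  overall fractions:",
      paste(sprintf("%s=%.3f", names(x$overall), x$overall), collapse = ", "),
      "\n")
  cat(sprintf("  %d/%d bins with significant non-uniform classification\n",
              sum(x$per_bin$significant), nrow(x$per_bin)))
  invisible(x)
}
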