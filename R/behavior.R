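LOCS <- c("top", "middle", "bottom")

#' Session-level behavioral performance
#'
#' Hit rate (correct detection and localization of a color change) per
#' change location, and correct-rejection rate, computed from completed
#' trials only, separately per trial type.
#'
#' @param trials A `trial_table`.
#' @param by `"change_location"` (default) or `"cue_location"`.
#' @return Data frame with one row per (trial type, location): hits,
#'   misses, hit rate (%), and per trial type the CR rate (%); undefined
#'   rates (zero denominator) are `NA`, never 0.
#' @export
session_performance <- function(trials, by = c("change_location",
                                               "cue_location")) {
  by <- match.arg(by)
  done <- trials[trials$completed, ]
  out <- list()
  for (tt in unique(done$trial_type)) {
    d <- done[done$trial_type == tt, ]
    chg <- d[d$change_location != "none", ]
    nochg <- d[d$change_location == "none", ]
    n_cr <- sum(nochg$outcome == "correct_rejection")
    n_fa <- sum(nochg$outcome == "false_alarm")
    cr_rate <- if (n_cr + n_fa > 0) 100 * n_cr / (n_cr + n_fa) else NA_real_
    for (loc in LOCS) {
      dl <- chg[chg[[by]] == loc, ]
      h <- sum(dl$outcome == "hit"); m <- sum(dl$outcome == "miss")
      out[[length(out) + 1]] <- data.frame(
        session_id = done$session_id[1], trial_type = tt, location = loc,
        n_hit = h, n_miss = m,
        hit_rate = if (h + m > 0) 100 * h / (h + m) else NA_real_,
        cr_rate = cr_rate)
    }
  }
  res <- do.call(rbind, out)
  class(res) <- c("session_performance", "data.frame")
  res
}

# rank locations by hit rate, undefined rates last, ties by display order
rank_locations <- function(rates) {
  key <- ifelse(is.na(rates), -Inf, rates)
  ord <- order(-key, match(names(rates), LOCS))
  names(rates)[ord]
}

#' Block-wise location preference labels
#'
#' Splits the session's completed trials into `n_blocks` equal consecutive
#' blocks, computes within each block the hit rate per change location from
#' no-cue change trials, and labels the locations "preferred",
#' "intermediate" and "least" by descending hit rate (ties and undefined
#' rates broken by display order: top before middle before bottom).
#'
#' @param trials A `trial_table`.
#' @param n_blocks Number of blocks.
#' @return Data frame with one row per (block, location): hit counts, hit
#'   rate and the assigned label.
#' @export
block_preference <- function(trials, n_blocks = 5L) {
  done <- trials[trials$completed, ]
  done <- done[order(done$trial_id), ]
  n <- nrow(done)
  if (n < n_blocks)
    stop("invalid-input: fewer completed trials than blocks", call. = FALSE)
  # consecutive blocks with sizes differing by at most one
  sizes <- largest_remainder(n, rep(1 / n_blocks, n_blocks))
  blk <- rep(seq_len(n_blocks), sizes)
  out <- list()
  for (b in seq_len(n_blocks)) {
    d <- done[blk == b, ]
    d <- d[d$trial_type == "no_cue" & d$change_location != "none", ]
    rates <- sapply(LOCS, function(loc) {
      dl <- d[d$change_location == loc, ]
      h <- sum(dl$outcome == "hit"); m <- sum(dl$outcome == "miss")
      if (h + m > 0) h / (h + m) else NA_real_
    })
    ranked <- rank_locations(rates)
    lab <- stats::setNames(c("preferred", "intermediate", "least"), ranked)
    out[[b]] <- data.frame(block = b, location = LOCS,
                           hit_rate = as.numeric(rates),
                           label = as.character(lab[LOCS]))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Session-level surrogate preferred location
#'
#' Counts per location how many blocks labeled it "preferred"; the highest
#' count wins, with ties resolved by display order (top, then middle, then
#' bottom). The medium and least-preferred locations follow from the lower
#' counts with the same tie rule.
#'
#' @param blocks Output of [block_preference()].
#' @return List with `preferred`, `ordered` (preferred, medium, least) and
#'   the per-location preferred-block `counts`.
#' @export
session_preference <- function(blocks) {
  pref <- blocks[blocks$label == "preferred", ]
  counts <- sapply(LOCS, function(l) sum(pref$location == l))
  ord <- order(-counts, match(LOCS, LOCS))
  ordered <- LOCS[ord]
  list(preferred = ordered[1], ordered = ordered, counts = counts)
}

#' Dataset-level preference fractions and block-count stability
#'
#' For each block count `s`, computes the fraction of all blocks of all
#' sessions in which each location was the block-preferred location, and
#' each session's surrogate preferred location. Stability across `s` is
#' reported (identical modal preferred location for every `s`), not
#' enforced.
#'
#' @param sessions List of `trial_table`s (one per session).
#' @param s_range Block counts to evaluate.
#' @return A `preference_result`: list with `fractions` (one row per `s`),
#'   `session_preferred` (sessions x s matrix), `modal` per `s`, and
#'   `stable`.
#' @export
preference_fractions <- function(sessions, s_range = 3:10) {
  if (length(sessions) < 1)
    stop("invalid-input: need >= 1 session", call. = FALSE)
  frac <- matrix(0, length(s_range), 3,
                 dimnames = list(paste0("s", s_range), LOCS))
  sess_pref <- matrix(NA_character_, length(sessions), length(s_range),
                      dimnames = list(NULL, paste0("s", s_range)))
  for (si in seq_along(s_range)) {
    s <- s_range[si]
    tally <- stats::setNames(numeric(3), LOCS)
    total <- 0
    for (k in seq_along(sessions)) {
      bl <- block_preference(sessions[[k]], n_blocks = s)
      pref_rows <- bl[bl$label == "preferred", ]
      for (l in pref_rows$location) tally[l] <- tally[l] + 1
      total <- total + s
      sess_pref[k, si] <- session_preference(bl)$preferred
    }
    frac[si, ] <- tally / total
  }
  modal <- apply(sess_pref, 2, function(v) {
    counts <- sapply(LOCS, function(l) sum(v == l))
    LOCS[order(-counts, match(LOCS, LOCS))][1]
  })
  structure(list(fractions = frac, session_preferred = sess_pref,
                 modal = modal, stable = length(unique(modal)) == 1,
                 s_range = s_range),
            class = "preference_result")
}

#' @export
print.preference_result <- function(x, ...) {
  cat("Block-preference analysis across", nrow(x$session_preferred),
      "session(s)\n")
  s5 <- which(x$s_range == 5)
  row <- if (length(s5) == 1) x$fractions[s5, ] else x$fractions[1, ]
  cat("  block fractions:",
      paste(sprintf("%s=%.1f%%", names(row), 100 * row), collapse = ", "),
      "\n")
  cat(sprintf("  modal preferred location stable over s=%d..%d: %s\n",
              min(x$s_range), max(x$s_range), x$stable))
  invisible(x)
}

#' Nonparametric tests of performance across locations
#'
#' Kruskal-Wallis omnibus test of per-session rates grouped by location,
#' followed by Dunn-type pairwise post hoc comparisons on the joint ranks
#' with Bonferroni control.
#'
#' @param rates Numeric per-session rates.
#' @param locations Location label per rate.
#' @return List with the omnibus `statistic`, `df`, `p_value`, a
#'   `degenerate` flag (identical data; p = 1), and a `pairwise` data
#'   frame of Dunn z statistics and adjusted p values.
#' @export
location_tests <- function(rates, locations) {
  locations <- droplevels(factor(locations))
  if (any(table(locations) < 2))
    stop("invalid-input: need >= 2 sessions per location", call. = FALSE)
  if (length(unique(rates)) == 1) {
    return(list(statistic = 0, df = nlevels(locations) - 1L, p_value = 1,
                degenerate = TRUE, pairwise = NULL))
  }
  kw <- stats::kruskal.test(rates, locations)
  # Dunn post hoc on joint ranks with tie correction
  n <- length(rates)
  rk <- rank(rates)
  ties <- table(rk)
  tie_corr <- sum(ties^3 - ties) / (12 * (n - 1))
  lev <- levels(locations)
  pairs <- utils::combn(lev, 2)
  n_comp <- ncol(pairs)
  pw <- lapply(seq_len(n_comp), function(i) {
    a <- pairs[1, i]; b <- pairs[2, i]
    na <- sum(locations == a); nb2 <- sum(locations == b)
    z <- (mean(rk[locations == a]) - mean(rk[locations == b])) /
      sqrt((n * (n + 1) / 12 - tie_corr) * (1 / na + 1 / nb2))
    data.frame(a = a, b = b, z = z,
               p_adj = min(2 * stats::pnorm(-abs(z)) * n_comp, 1))
  })
  list(statistic = unname(kw$statistic), df = unname(kw$parameter),
       p_value = kw$p.value, degenerate = FALSE,
       pairwise = do.call(rbind, pw))
}
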