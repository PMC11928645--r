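# number of elements of sorted vector `v` strictly below each x
n_below <- function(x, v) findInterval(x, v, left.open = TRUE)

#' Sliding-window bin grid
#'
#' Defines 200 ms bins advanced in 20 ms steps (the defaults) across an
#' analysis window aligned to a trial event. Bin intervals are half-open
#' `[t, t + width)` anchored at the window start; bin *centers* are the
#' reported timestamps, so a reported time of t reflects spikes from
#' t - width/2 to t + width/2 (a 100 ms smear either side at defaults —
#' apparent effects can precede an event by up to half a bin).
#'
#' @param align_event Trial-table event column to align to (e.g.
#'   `"sample_on"`, `"cue_on"`).
#' @param window Numeric `(start, end)` in seconds relative to the align
#'   event; bins start at `window[1]` and the last bin ends at or before
#'   `window[2]`.
#' @param bin_width_s Bin width in seconds.
#' @param step_s Step between consecutive bin starts in seconds.
#' @return An object of class `bin_grid` with precomputed `starts` and
#'   `centers`.
#' @examples
#' g <- bin_grid("sample_on", c(-0.7, 1.9))
#' length(g$centers)
#' @export
bin_grid <- function(align_event = "sample_on", window = c(-0.7, 1.9),
                     bin_width_s = 0.2, step_s = 0.02) {
  if (bin_width_s <= 0 || step_s <= 0)
    stop("invalid-config: bin_width_s and step_s must be > 0", call. = FALSE)
  if (window[1] >= window[2])
    stop("invalid-config: window start must be < end", call. = FALSE)
  starts <- seq(window[1], window[2] - bin_width_s + 1e-12, by = step_s)
  if (length(starts) == 0)
    stop("invalid-config: window too short for one bin", call. = FALSE)
  structure(list(align_event = align_event, window = window,
                 bin_width_s = bin_width_s, step_s = step_s,
                 starts = starts, centers = starts + bin_width_s / 2),
            class = "bin_grid")
}

#' Bin spike trains into a firing-rate tensor
#'
#' Counts spikes per unit, trial and sliding bin and converts counts to
#' rates (spikes/s). A spike can contribute to several overlapping bins;
#' bins are half-open `[t, t + width)` in time relative to the trial's
#' align event.
#'
#' @param spikes Data frame `unit_id`, `trial_id`, `spike_time_s` (seconds
#'   from trial start).
#' @param trials A `trial_table`; must contain the grid's align event column.
#' @param grid A [bin_grid()].
#' @param unit_ids Optional subset/order of units; defaults to the units
#'   present in `spikes`.
#' @return A `rate_tensor`: numeric array `[units x trials x bins]` with
#'   `unit_ids`, `trial_ids` and `grid` attributes.
#' @export
bin_firing_rates <- function(spikes, trials, grid, unit_ids = NULL) {
  stopifnot(inherits(grid, "bin_grid"))
  ev <- trials[[grid$align_event]]
  if (is.null(ev))
    stop("invalid-input: trials lack event column '", grid$align_event, "'",
         call. = FALSE)
  bad <- trials$trial_id[!is.finite(ev)]
  if (length(bad) > 0)
    stop("missing align event '", grid$align_event, "' for trial(s): ",
         paste(utils::head(bad, 10), collapse = ", "), call. = FALSE)
  if (is.null(unit_ids)) unit_ids <- sort(unique(as.character(spikes$unit_id)))
  trial_ids <- trials$trial_id
  nu <- length(unit_ids); nt <- length(trial_ids); nb <- length(grid$starts)
  x <- array(0, dim = c(nu, nt, nb),
             dimnames = list(unit_ids, trial_ids, NULL))
  if (nrow(spikes) > 0) {
    ev_of <- stats::setNames(ev, trial_ids)
    keep <- spikes$trial_id %in% trial_ids & spikes$unit_id %in% unit_ids
    sp <- spikes[keep, ]
    rel <- sp$spike_time_s - ev_of[as.character(sp$trial_id)]
    ui <- match(as.character(sp$unit_id), unit_ids)
    ti <- match(sp$trial_id, trial_ids)
    ends <- grid$starts + grid$bin_width_s
    key <- split(seq_along(rel), list(ui = ui, ti = ti), drop = TRUE)
    for (nm in names(key)) {
      idx <- key[[nm]]
      tsort <- sort(rel[idx])
      # half-open [start, end): #(t < end) - #(t < start)
      cnt <- n_below(ends, tsort) - n_below(grid$starts, tsort)
      p <- as.integer(strsplit(nm, "[.]")[[1]])
      x[p[1], p[2], ] <- cnt / grid$bin_width_s
    }
  }
  structure(x, unit_ids = unit_ids, trial_ids = trial_ids, grid = grid,
            class = c("rate_tensor", "array"))
}

#' @export
print.rate_tensor <- function(x, ...) {
  d <- dim(x)
  g <- attr(x, "grid")
  cat(sprintf(
    "Rate tensor: %d units x %d trials x %d bins (%.0f ms bins, %.0f ms step, aligned to %s)\n",
    d[1], d[2], d[3], 1000 * g$bin_width_s, 1000 * g$step_s, g$align_event))
  invisible(x)
}

#' Select non-overlapping bins from a sliding grid
#'
#' Whenever consecutive bins enter one statistical test, bins must not
#' overlap; for 200 ms bins at a 20 ms step this keeps every 10th bin.
#'
#' @param grid A [bin_grid()].
#' @param stride_bins Bins to advance between selections; defaults to
#'   `ceiling(bin_width / step)`, the smallest disjoint stride.
#' @return Integer vector of bin indices with pairwise-disjoint intervals.
#' @export
select_nonoverlapping <- function(grid, stride_bins = NULL) {
  stopifnot(inherits(grid, "bin_grid"))
  if (is.null(stride_bins))
    stride_bins <- as.integer(ceiling(grid$bin_width_s / grid$step_s - 1e-9))
  if (stride_bins * grid$step_s < grid$bin_width_s - 1e-12)
    stop("invalid-argument: stride_bins * step_s must be >= bin_width_s",
         call. = FALSE)
  seq(1L, length(grid$starts), by = stride_bins)
}

#' Apply the unit and trial inclusion filters
#'
#' Retains completed (non-aborted) trials, drops units whose average ITI
#' firing rate is below `min_iti_rate_hz`, and reports which condition
#' groups fall below `min_trials_per_condition`.
#'
#' @param spikes Spike data frame.
#' @param trials A `trial_table`.
#' @param condition Factor (or column name) defining the tested conditions;
#'   default is trial type crossed with cue location.
#' @param min_trials_per_condition Minimum completed trials per condition.
#' @param min_iti_rate_hz Minimum mean firing rate during the ITI epoch
#'   `[0, iti_s)`.
#' @param iti_s ITI duration in seconds.
#' @return List with `unit_ids`, `trial_ids`, `dropped_units`,
#'   `dropped_conditions`, and per-unit `iti_rate_hz`.
#' @export
apply_inclusion_filters <- function(spikes, trials, condition = NULL,
                                    min_trials_per_condition = 20L,
                                    min_iti_rate_hz = 0.5, iti_s = 2.0) {
  done <- trials[trials$completed, ]
  if (is.null(condition))
    condition <- interaction(done$trial_type, done$cue_location, drop = TRUE)
  else if (is.character(condition) && length(condition) == 1)
    condition <- factor(done[[condition]])
  else condition <- factor(condition)
  stopifnot(length(condition) == nrow(done))
  cond_n <- table(condition)
  bad_cond <- names(cond_n)[cond_n < min_trials_per_condition]
  keep_trials <- done$trial_id[!(condition %in% bad_cond)]

  units <- sort(unique(as.character(spikes$unit_id)))
  in_iti <- spikes$spike_time_s < iti_s & spikes$trial_id %in% done$trial_id
  n_iti <- table(factor(as.character(spikes$unit_id[in_iti]), levels = units))
  iti_rate <- as.numeric(n_iti) / (nrow(done) * iti_s)
  names(iti_rate) <- units
  keep_units <- units[iti_rate >= min_iti_rate_hz]
  if (length(keep_units) == 0 && length(units) > 0)
    stop("empty-selection: no unit meets the ITI rate criterion",
         call. = FALSE)
  if (length(keep_trials) == 0)
    stop("empty-selection: no condition meets the trial-count criterion",
         call. = FALSE)
  list(unit_ids = keep_units, trial_ids = keep_trials,
       dropped_units = setdiff(units, keep_units),
       dropped_conditions = bad_cond, iti_rate_hz = iti_rate)
}

#' Keep the first k completed trials of every condition
#'
#' Trial counts differ between conditions; analyses therefore use only the
#' first `k` completed trials of each condition, in chronological session
#' order, so every condition contributes identically many observations.
#'
#' @param trials A `trial_table`.
#' @param condition Factor (aligned with the completed trials of `trials`)
#'   defining conditions.
#' @param k Trials to keep per condition.
#' @return The subsetted `trial_table`, in original session order.
#' @export
subsample_first_k <- function(trials, condition, k = 20L) {
  done <- trials[trials$completed, ]
  condition <- factor(condition)
  stopifnot(length(condition) == nrow(done))
  short <- table(condition) < k
  if (any(short))
    stop("invalid-input: condition(s) with fewer than ", k, " trials: ",
         paste(names(which(short)), collapse = ", "), call. = FALSE)
  ord <- order(done$trial_id)
  done <- done[ord, ]
  condition <- condition[ord]
  keep <- unlist(lapply(levels(condition), function(l)
    which(condition == l)[seq_len(k)]))
  out <- done[sort(keep), ]
  class(out) <- c("trial_table", "data.frame")
  out
}
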