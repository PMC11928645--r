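#' Color-information attentional-shift analysis for one location
#'
#' Runs the full delta-PEV pipeline at one display location: color PEV time
#' courses (on non-overlapping bins) for trials with the cue at that
#' location, for no-cue trials, and for trials with the cue elsewhere, each
#' subsampled to the first `k` completed trials per color, then combined
#' into gain / loss / overall shift matrices.
#'
#' With `location = "all"`, the shift is computed at each of the three
#' locations and averaged per unit and bin, so every unit contributes the
#' shift at its own (possibly unknown) tuned location — this is the
#' population-level form the across-unit sign-rank tests are applied to.
#'
#' @param trials A `trial_table`.
#' @param spikes Spike data frame.
#' @param location `"top"`, `"middle"`, `"bottom"`, or `"all"` (per-unit
#'   average over the three analyzed locations).
#' @param grid A [bin_grid()]; only its non-overlapping bins are used.
#' @param k Trials per color condition (first-k subsampling).
#' @param unit_ids Optional unit subset/order.
#' @return A `shift_table` (see [attentional_shift()]) with bin centers.
#' @export
color_shift_analysis <- function(trials, spikes, location, grid,
                                 k = 20L, unit_ids = NULL) {
  stopifnot(location %in% c("top", "middle", "bottom", "all"))
  if (location == "all") {
    per_loc <- lapply(c("top", "middle", "bottom"), function(l)
      color_shift_analysis(trials, spikes, l, grid, k = k,
                           unit_ids = unit_ids))
    avg <- function(field)
      Reduce(`+`, lapply(per_loc, `[[`, field)) / length(per_loc)
    return(structure(list(gain = avg("gain"), loss = avg("loss"),
                          overall = avg("overall"),
                          centers = per_loc[[1]]$centers),
                     class = "shift_table"))
  }
  if (is.null(unit_ids)) unit_ids <- sort(unique(as.character(spikes$unit_id)))
  nov <- select_nonoverlapping(grid)
  col_lab <- paste0("sample_color_", location)
  done <- trials[trials$completed, ]
  sets <- list(
    precue  = done[done$trial_type == "pre_cue" &
                     done$cue_location == location, ],
    nocue   = done[done$trial_type == "no_cue", ],
    cueother = done[done$trial_type == "pre_cue" &
                      done$cue_location != location, ])
  pevs <- lapply(sets, function(tt) {
    tt2 <- subsample_first_k(tt, tt[[col_lab]], k = k)
    rt <- bin_firing_rates(spikes, tt2, grid, unit_ids = unit_ids)
    pv <- pev_timecourse(rt, tt2[[col_lab]])
    pv$pev[, nov, drop = FALSE]
  })
  attentional_shift(pevs$precue, pevs$nocue, pevs$cueother,
                    centers = grid$centers[nov])
}
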