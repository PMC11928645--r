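#' Task protocol configuration
#'
#' Timing and structure of the delayed change-detection task: an inter-trial
#' interval, then (on pre-cue trials) a 200 ms spatial cue followed by a
#' 500 ms delay, or (on no-cue trials) a 700 ms delay, then a 400 ms sample
#' array of three colored squares (top/middle/bottom), a 1100 ms memory
#' delay, and a 400 ms compare array. The two trial-type paths are
#' constructed so that sample onset is time-locked 0.7 s after initiation in
#' both, which the downstream alignment relies on.
#'
#' @param iti_s Inter-trial interval, seconds.
#' @param cue_dur_s Pre-cue duration, seconds.
#' @param postcue_delay_s Delay after cue offset, seconds.
#' @param nocue_delay_s Delay replacing cue + post-cue delay on no-cue trials.
#' @param sample_dur_s Sample array duration, seconds.
#' @param memory_delay_s Memory delay, seconds.
#' @param compare_dur_s Compare array duration, seconds.
#' @param n_trials Trials per session.
#' @param n_palette_colors Size of the session color palette from which each
#'   location's color pair is drawn without replacement.
#' @return An object of class `protocol_config`.
#' @examples
#' p <- protocol_config()
#' epoch_times(p)
#' @export
protocol_config <- function(iti_s = 2.0, cue_dur_s = 0.2, postcue_delay_s = 0.5,
                            nocue_delay_s = 0.7, sample_dur_s = 0.4,
                            memory_delay_s = 1.1, compare_dur_s = 0.4,
                            n_trials = 850L, n_palette_colors = 15L) {
  durs <- c(iti_s, cue_dur_s, postcue_delay_s, nocue_delay_s,
            sample_dur_s, memory_delay_s, compare_dur_s)
  if (!all(is.finite(durs)) || any(durs <= 0))
    stop("invalid-config: all protocol durations must be positive", call. = FALSE)
  if (abs((cue_dur_s + postcue_delay_s) - nocue_delay_s) > 1e-9)
    stop("invalid-config: cue_dur_s + postcue_delay_s must equal nocue_delay_s ",
         "so sample onset is time-locked across trial types", call. = FALSE)
  if (!is.numeric(n_trials) || n_trials < 1)
    stop("invalid-config: n_trials must be >= 1", call. = FALSE)
  structure(list(iti_s = iti_s, cue_dur_s = cue_dur_s,
                 postcue_delay_s = postcue_delay_s,
                 nocue_delay_s = nocue_delay_s, sample_dur_s = sample_dur_s,
                 memory_delay_s = memory_delay_s, compare_dur_s = compare_dur_s,
                 n_trials = as.integer(n_trials),
                 locations = c("top", "middle", "bottom"),
                 n_palette_colors = as.integer(n_palette_colors)),
            class = "protocol_config")
}

#' Event times implied by a protocol
#'
#' Times are seconds from trial start, where the trial clock starts at the
#' onset of the inter-trial interval and the bird initiates at `iti_s`.
#'
#' @param protocol A [protocol_config()].
#' @param trial_type `"pre_cue"` or `"no_cue"`; on no-cue trials `cue_on` and
#'   `cue_off` are `NA`.
#' @return Named numeric vector with `init`, `cue_on`, `cue_off`, `sample_on`,
#'   `sample_off`, `compare_on`, `choice_on`.
#' @export
epoch_times <- function(protocol, trial_type = c("pre_cue", "no_cue")) {
  trial_type <- match.arg(trial_type)
  init <- protocol$iti_s
  sample_on <- init + protocol$nocue_delay_s
  sample_off <- sample_on + protocol$sample_dur_s
  compare_on <- sample_off + protocol$memory_delay_s
  choice_on <- compare_on + protocol$compare_dur_s
  if (trial_type == "pre_cue") {
    cue_on <- init; cue_off <- init + protocol$cue_dur_s
  } else {
    cue_on <- NA_real_; cue_off <- NA_real_
  }
  c(init = init, cue_on = cue_on, cue_off = cue_off, sample_on = sample_on,
    sample_off = sample_off, compare_on = compare_on, choice_on = choice_on)
}

#' @export
print.protocol_config <- function(x, ...) {
  cat("Change-detection task protocol\n")
  cat(sprintf("  ITI %.1f s | cue %.0f ms + delay %.0f ms (pre-cue) / delay %.0f ms (no-cue)\n",
              x$iti_s, 1000 * x$cue_dur_s, 1000 * x$postcue_delay_s,
              1000 * x$nocue_delay_s))
  cat(sprintf("  sample %.0f ms | memory delay %.0f ms | compare %.0f ms\n",
              1000 * x$sample_dur_s, 1000 * x$memory_delay_s,
              1000 * x$compare_dur_s))
  cat(sprintf("  %d trials/session, locations: %s, %d palette colors\n",
              x$n_trials, paste(x$locations, collapse = "/"),
              x$n_palette_colors))
  invisible(x)
}
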