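#' Behavioral agent configuration
#'
#' The agent attends exactly one location per trial: the cued location on
#' pre-cue trials, and on no-cue trials either a fixed preferred location
#' (`strategy = "fixed"`) or a location it occasionally switches between
#' blocks of trials (`strategy = "switching"`). Outcomes are Bernoulli:
#' a change at the attended location is detected with `p_hit_attended`,
#' a change elsewhere with `p_hit_unattended`, and no-change trials are
#' correctly rejected with `p_cr`.
#'
#' @param strategy `"fixed"` or `"switching"`.
#' @param fixed_location Attended location for the fixed strategy.
#' @param switch_hazard Probability of switching to a different location at
#'   each block boundary (switching strategy).
#' @param block_len Trials per attention block for the switching strategy;
#'   `block_len = 1` with `switch_hazard = 1` attends a uniformly random
#'   location on every trial.
#' @param p_hit_attended,p_hit_unattended,p_cr Outcome probabilities in
#'   `[0, 1]`.
#' @return An object of class `agent_config`.
#' @examples
#' agent_config("fixed", fixed_location = "top")
#' @export
agent_config <- function(strategy = c("fixed", "switching"),
                         fixed_location = NULL, switch_hazard = 0.5,
                         block_len = 50L, p_hit_attended = 0.95,
                         p_hit_unattended = 0.05, p_cr = 0.95) {
  strategy <- match.arg(strategy)
  p <- c(switch_hazard, p_hit_attended, p_hit_unattended, p_cr)
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1))
    stop("invalid-config: probabilities must be in [0, 1]", call. = FALSE)
  if (strategy == "fixed") {
    if (is.null(fixed_location) ||
        !fixed_location %in% c("top", "middle", "bottom"))
      stop("invalid-config: strategy 'fixed' requires fixed_location in ",
           "top/middle/bottom", call. = FALSE)
  }
  if (block_len < 1) stop("invalid-config: block_len must be >= 1", call. = FALSE)
  structure(list(strategy = strategy, fixed_location = fixed_location,
                 switch_hazard = switch_hazard,
                 block_len = as.integer(block_len),
                 p_hit_attended = p_hit_attended,
                 p_hit_unattended = p_hit_unattended, p_cr = p_cr),
            class = "agent_config")
}
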