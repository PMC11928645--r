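#' Construct a single unit specification
#'
#' A unit is an epoch-wise homogeneous Poisson spiker whose rate is
#' `baseline_hz` multiplied by a spatial gain (when the trial's cue /
#' attended location matches its preferred location) and a color gain (when
#' color 2 is shown at its color-tuned location). The color-gain contrast is
#' raised to the power `attn_gain` on trials where the attended location is
#' the unit's color-tuned location, which is the attentional modulation the
#' downstream delta-PEV analyses estimate.
#'
#' @param unit_id Character identifier.
#' @param class One of `"location_only"`, `"color_only"`, `"both"`, `"untuned"`.
#' @param baseline_hz Baseline firing rate (spikes/s).
#' @param pref_location Preferred (cue/attended) location or `NA`.
#' @param loc_gain Multiplicative spatial gain (> 0).
#' @param color_location Location whose color the unit is tuned to, or `NA`.
#' @param color_gain Multiplicative gain for color 2 at `color_location` (> 0).
#' @param attn_gain Exponent (>= 1) applied to the color gain at the attended
#'   location; 1 means no attentional modulation.
#' @return An object of class `unit_spec`.
#' @export
unit_spec <- function(unit_id, class = "untuned", baseline_hz = 8,
                      pref_location = NA_character_, loc_gain = 1,
                      color_location = NA_character_, color_gain = 1,
                      attn_gain = 1) {
  class <- match.arg(class, c("location_only", "color_only", "both", "untuned"))
  if (!is.finite(baseline_hz) || baseline_hz < 0)
    stop("invalid-config: baseline_hz must be >= 0", call. = FALSE)
  if (loc_gain <= 0 || color_gain <= 0)
    stop("invalid-config: gains must be > 0", call. = FALSE)
  if (attn_gain < 1)
    stop("invalid-config: attn_gain must be >= 1", call. = FALSE)
  structure(list(unit_id = as.character(unit_id), class = class,
                 baseline_hz = baseline_hz, pref_location = pref_location,
                 loc_gain = loc_gain, color_location = color_location,
                 color_gain = color_gain, attn_gain = attn_gain,
                 noise_model = "poisson"),
            class = "unit_spec")
}

# Largest-remainder apportionment of n into length(frac) integer counts.
largest_remainder <- function(n, frac) {
  raw <- n * frac
  counts <- floor(raw)
  rem <- n - sum(counts)
  if (rem > 0) {
    ord <- order(raw - counts, decreasing = TRUE)
    counts[ord[seq_len(rem)]] <- counts[ord[seq_len(rem)]] + 1
  }
  as.integer(counts)
}

#' Generate a tuned unit population
#'
#' Draws `n_units` unit specifications whose tuning-class composition follows
#' `class_fractions` via largest-remainder rounding, so e.g. 100 units with
#' fractions (0.29, 0.04, 0.23, 0.44) give exactly 29/4/23/44 units per
#' class. Baseline rates are log-normal (median ~8 spikes/s) clamped at the
#' 0.5 spikes/s inclusion floor; preferred and color-tuned locations are
#' drawn uniformly.
#'
#' @param n_units Number of units.
#' @param class_fractions Named fractions over
#'   `location_only`, `color_only`, `both`, `untuned`; must sum to 1.
#' @param seed Integer seed; identical seeds give identical populations.
#' @param loc_gain,color_gain,attn_gain Tuning parameters passed to every
#'   tuned unit (see [unit_spec()]).
#' @return A list of `unit_spec` objects, classed `unit_population`.
#' @examples
#' pop <- make_population(20, seed = 1)
#' table(vapply(pop, `[[`, "", "class"))
#' @export
make_population <- function(n_units,
                            class_fractions = c(location_only = 0.29,
                                                color_only = 0.04,
                                                both = 0.23, untuned = 0.44),
                            seed = 1L, loc_gain = 2, color_gain = 1.5,
                            attn_gain = 2) {
  classes <- c("location_only", "color_only", "both", "untuned")
  if (is.null(names(class_fractions))) names(class_fractions) <- classes
  if (!setequal(names(class_fractions), classes))
    stop("invalid-config: class_fractions must be named over ",
         paste(classes, collapse = ", "), call. = FALSE)
  frac <- as.numeric(class_fractions[classes])
  if (abs(sum(frac) - 1) > 1e-9)
    stop("invalid-config: class_fractions must sum to 1", call. = FALSE)
  counts <- largest_remainder(as.integer(n_units), frac)
  locs <- c("top", "middle", "bottom")
  pop <- with_seed(seed, {
    cls <- rep(classes, counts)
    lapply(seq_len(n_units), function(i) {
      k <- cls[i]
      base <- max(0.5, exp(rnorm(1, log(8), 0.35)))
      pl <- if (k %in% c("location_only", "both")) sample(locs, 1) else NA_character_
      cl <- if (k %in% c("color_only", "both")) sample(locs, 1) else NA_character_
      unit_spec(sprintf("u%03d", i), class = k, baseline_hz = base,
                pref_location = pl,
                loc_gain = if (is.na(pl)) 1 else loc_gain,
                color_location = cl,
                color_gain = if (is.na(cl)) 1 else color_gain,
                attn_gain = if (is.na(cl)) 1 else attn_gain)
    })
  })
  structure(pop, class = "unit_population")
}

#' @export
print.unit_population <- function(x, ...) {
  cls <- vapply(x, `[[`, "", "class")
  cat(sprintf("Unit population: %d units (%s)\n", length(x),
              paste(sprintf("%s=%d", names(table(cls)), table(cls)),
                    collapse = ", ")))
  invisible(x)
}
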