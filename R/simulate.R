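#' Simulate a complete task session
#'
#' Generates a trial table (balanced, pseudorandomized conditions), a
#' behavioral outcome per trial from the agent model, and Poisson spike
#' trains for every unit in the population. Conditions are balanced so that
#' per (trial type, cue location, change/no-change) cell the counts differ by
#' at most one, cue locations never repeat more than twice in a row among
#' pre-cue trials, and 50% of trials of each type contain a color change
#' (at the cued location on pre-cue trials, at a balanced random location on
#' no-cue trials).
#'
#' Firing rates are epoch-wise homogeneous Poisson: baseline during the ITI,
#' a visual/spatial gain while the cue is on screen (and through the
#' post-cue delay) when the cue is at the unit's preferred location, and,
#' from sample onset through the compare phase, a spatial gain keyed to the
#' trial's *attended* location plus a color gain keyed to the sample color
#' at the unit's color-tuned location. The color contrast is amplified
#' (raised to `attn_gain`) when the attended location is the tuned location.
#'
#' @param population A `unit_population` (possibly empty, for
#'   behavior-only simulations).
#' @param protocol A [protocol_config()].
#' @param agent An [agent_config()].
#' @param seed Master integer seed; trials, agent and spikes draw from named
#'   substreams so each component is reproducible in isolation.
#' @param session_id Session identifier string.
#' @return A list of class `crow_session` with elements `trials` (a
#'   `trial_table` data frame), `spikes` (data frame `unit_id`, `trial_id`,
#'   `spike_time_s`), and the three configs.
#' @examples
#' s <- simulate_session(make_population(5, seed = 1),
#'                       protocol_config(n_trials = 48),
#'                       agent_config("fixed", fixed_location = "top"),
#'                       seed = 7)
#' table(s$trials$trial_type, s$trials$outcome)
#' @export
simulate_session <- function(population, protocol = protocol_config(),
                             agent = agent_config("fixed", fixed_location = "top"),
                             seed = 1L, session_id = "s01") {
  stopifnot(inherits(protocol, "protocol_config"),
            inherits(agent, "agent_config"))
  if (protocol$n_trials < 1)
    stop("invalid-config: n_trials must be >= 1", call. = FALSE)
  trials <- build_trial_table(protocol, substream_seed(seed, "trials"),
                              session_id)
  trials <- apply_agent(trials, agent, substream_seed(seed, "agent"))
  spikes <- generate_spikes(population, trials, protocol,
                            substream_seed(seed, "spikes"))
  structure(list(trials = trials, spikes = spikes, population = population,
                 protocol = protocol, agent = agent, seed = seed),
            class = "crow_session")
}

# Balanced, pseudorandomized trial conditions for one session.
build_trial_table <- function(protocol, seed, session_id) {
  n <- protocol$n_trials
  locs <- protocol$locations
  with_seed(seed, {
    # condition cells with largest-remainder balanced counts
    half <- largest_remainder(n, c(0.5, 0.5))
    n_pre <- half[1]; n_no <- half[2]
    pre_counts <- largest_remainder(n_pre, rep(1 / 6, 6))
    no_counts <- largest_remainder(n_no, c(1 / 6, 1 / 6, 1 / 6, 1 / 2))
    rows <- list()
    k <- 1
    for (i in seq_along(locs)) for (chg in c(TRUE, FALSE)) {
      m <- pre_counts[(i - 1) * 2 + (2 - chg)]
      if (m > 0) {
        rows[[k]] <- data.frame(trial_type = "pre_cue", cue_location = locs[i],
                                change = chg,
                                change_location = ifelse(chg, locs[i], "none"))
        rows[[k]] <- rows[[k]][rep(1, m), ]
        k <- k + 1
      }
    }
    for (i in seq_along(locs)) {
      m <- no_counts[i]
      if (m > 0) {
        rows[[k]] <- data.frame(trial_type = "no_cue", cue_location = "none",
                                change = TRUE, change_location = locs[i])
        rows[[k]] <- rows[[k]][rep(1, m), ]
        k <- k + 1
      }
    }
    if (no_counts[4] > 0) {
      rows[[k]] <- data.frame(trial_type = "no_cue", cue_location = "none",
                              change = FALSE, change_location = "none")
      rows[[k]] <- rows[[k]][rep(1, no_counts[4]), ]
    }
    tab <- do.call(rbind, rows)
    # per condition cell, balanced color assignment per location
    cell <- interaction(tab$trial_type, tab$cue_location, tab$change_location,
                        drop = TRUE)
    for (loc in locs) {
      col <- integer(nrow(tab))
      for (cl in levels(cell)) {
        idx <- which(cell == cl)
        col[idx] <- sample(rep_len(c(1L, 2L), length(idx)))
      }
      tab[[paste0("sample_color_", loc)]] <- col
    }
    tab <- tab[sample.int(nrow(tab)), ]
    tab <- fix_cue_runs(tab)
    rownames(tab) <- NULL
    for (loc in locs) {
      cc <- tab[[paste0("sample_color_", loc)]]
      flip <- tab$change_location == loc
      cc[flip] <- 3L - cc[flip]
      tab[[paste0("compare_color_", loc)]] <- cc
    }
    ev_pre <- epoch_times(protocol, "pre_cue")
    ev_no <- epoch_times(protocol, "no_cue")
    is_pre <- tab$trial_type == "pre_cue"
    tab$cue_on <- ifelse(is_pre, ev_pre["cue_on"], ev_no["cue_on"])
    tab$cue_off <- ifelse(is_pre, ev_pre["cue_off"], ev_no["cue_off"])
    tab$sample_on <- ev_pre[["sample_on"]]
    tab$sample_off <- ev_pre[["sample_off"]]
    tab$compare_on <- ev_pre[["compare_on"]]
    tab$choice_on <- ev_pre[["choice_on"]]
    tab$trial_id <- seq_len(nrow(tab))
    tab$session_id <- session_id
    tab$completed <- TRUE
    tab$change <- NULL
    cols <- c("trial_id", "session_id", "trial_type", "cue_location",
              paste0("sample_color_", locs), paste0("compare_color_", locs),
              "change_location", "cue_on", "cue_off", "sample_on",
              "sample_off", "compare_on", "choice_on", "completed")
    tab <- tab[, cols]
    class(tab) <- c("trial_table", "data.frame")
    tab
  })
}

# Enforce "no more than two consecutive pre-cue trials with the same cue
# location" by deterministically swapping forward within the pre-cue
# subsequence.
fix_cue_runs <- function(tab) {
  pre_idx <- which(tab$trial_type == "pre_cue")
  if (length(pre_idx) < 3) return(tab)
  for (j in 3:length(pre_idx)) {
    a <- pre_idx[j - 2]; b <- pre_idx[j - 1]; cc <- pre_idx[j]
    if (tab$cue_location[a] == tab$cue_location[b] &&
        tab$cue_location[b] == tab$cue_location[cc]) {
      later <- pre_idx[pre_idx > cc]
      swap <- later[tab$cue_location[later] != tab$cue_location[cc]]
      if (length(swap) > 0) {
        s <- swap[1]
        tmp <- tab[cc, ]; tab[cc, ] <- tab[s, ]; tab[s, ] <- tmp
      }
    }
  }
  tab
}

# Attach attended location, response and outcome columns.
apply_agent <- function(trials, agent, seed) {
  n <- nrow(trials)
  with_seed(seed, {
    locs <- c("top", "middle", "bottom")
    att_nocue <- character(n)
    if (agent$strategy == "fixed") {
      att_nocue[] <- agent$fixed_location
    } else {
      cur <- sample(locs, 1)
      blk <- (seq_len(n) - 1L) %/% agent$block_len
      for (i in seq_len(n)) {
        if (i > 1 && blk[i] != blk[i - 1] && runif(1) < agent$switch_hazard)
          cur <- sample(setdiff(locs, cur), 1)
        att_nocue[i] <- cur
      }
    }
    is_pre <- trials$trial_type == "pre_cue"
    trials$attended_location <- ifelse(is_pre, trials$cue_location, att_nocue)
    chg <- trials$change_location
    u <- runif(n)
    outcome <- character(n)
    response <- character(n)
    for (i in seq_len(n)) {
      if (chg[i] == "none") {
        if (u[i] < agent$p_cr) {
          outcome[i] <- "correct_rejection"; response[i] <- "center"
        } else {
          outcome[i] <- "false_alarm"; response[i] <- trials$attended_location[i]
        }
      } else {
        p <- if (chg[i] == trials$attended_location[i]) agent$p_hit_attended
             else agent$p_hit_unattended
        if (u[i] < p) {
          outcome[i] <- "hit"; response[i] <- chg[i]
        } else {
          outcome[i] <- "miss"; response[i] <- "center"
        }
      }
    }
    trials$response_location <- response
    trials$outcome <- outcome
    trials
  })
}

# Epoch-wise homogeneous Poisson spike trains for all units x trials.
generate_spikes <- function(population, trials, protocol, seed) {
  empty <- data.frame(unit_id = character(), trial_id = integer(),
                      spike_time_s = numeric())
  if (length(population) == 0) return(empty)
  n <- nrow(trials)
  init <- protocol$iti_s
  bounds <- c(0, init, init + protocol$cue_dur_s, trials$sample_on[1],
              trials$sample_off[1], trials$compare_on[1], trials$choice_on[1])
  durs <- diff(bounds)
  n_ep <- length(durs)
  is_pre <- trials$trial_type == "pre_cue"
  with_seed(seed, {
    out <- vector("list", length(population))
    for (ui in seq_along(population)) {
      u <- population[[ui]]
      gain <- matrix(1, n, n_ep)
      if (!is.na(u$pref_location)) {
        cue_match <- is_pre & trials$cue_location == u$pref_location
        att_match <- trials$attended_location == u$pref_location
        gain[cue_match, 2:3] <- gain[cue_match, 2:3] * u$loc_gain
        gain[att_match, 4:6] <- gain[att_match, 4:6] * u$loc_gain
      }
      if (!is.na(u$color_location)) {
        col2 <- trials[[paste0("sample_color_", u$color_location)]] == 2L
        att <- trials$attended_location == u$color_location
        expo <- ifelse(att, u$attn_gain, 1)
        cg <- ifelse(col2, u$color_gain^expo, 1)
        gain[, 4:6] <- gain[, 4:6] * cg
      }
      lam <- sweep(gain * u$baseline_hz, 2, durs, `*`)
      counts <- matrix(rpois(n * n_ep, lam), n, n_ep)
      tot <- sum(counts)
      if (tot == 0) next
      cvec <- as.vector(t(counts))       # trial-major, epoch within trial
      ep_rep <- rep(rep(seq_len(n_ep), n), cvec)
      tr_rep <- rep(rep(seq_len(n), each = n_ep), cvec)
      tt <- bounds[ep_rep] + runif(tot) * durs[ep_rep]
      ord <- order(tr_rep, tt)
      out[[ui]] <- data.frame(unit_id = u$unit_id,
                              trial_id = trials$trial_id[tr_rep[ord]],
                              spike_time_s = tt[ord])
    }
    res <- do.call(rbind, out)
    if (is.null(res)) empty else res
  })
}

#' @export
print.crow_session <- function(x, ...) {
  cat(sprintf("Simulated session %s: %d trials, %d units, %d spikes\n",
              x$trials$session_id[1], nrow(x$trials), length(x$population),
              nrow(x$spikes)))
  ot <- table(x$trials$outcome)
  cat("  outcomes:", paste(sprintf("%s=%d", names(ot), ot), collapse = ", "),
      "\n")
  invisible(x)
}
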