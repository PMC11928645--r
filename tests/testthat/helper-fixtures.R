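# Shared synthetic fixtures, built once per test run on first use.
.fx <- new.env()

fixture <- function(name) {
  if (!is.null(.fx[[name]])) return(.fx[[name]])
  .fx[[name]] <- switch(
    name,
    # deterministic fixed-top agent with tuned units
    fixed = simulate_session(
      make_population(20, seed = 2),
      protocol_config(n_trials = 240),
      agent_config("fixed", fixed_location = "top", p_hit_attended = 1,
                   p_hit_unattended = 0, p_cr = 1),
      seed = 7, session_id = "fx_fixed"),
    # uniformly switching agent (new attended location every trial)
    switch = simulate_session(
      make_population(20, seed = 3),
      protocol_config(n_trials = 240),
      agent_config("switching", switch_hazard = 1, block_len = 1L,
                   p_hit_attended = 0.9, p_hit_unattended = 0.1),
      seed = 11, session_id = "fx_switch"),
    # untuned units, no attentional modulation, guessing agent
    null = simulate_session(
      make_population(16, class_fractions = c(location_only = 0,
                                              color_only = 0, both = 0,
                                              untuned = 1),
                      seed = 4, attn_gain = 1),
      protocol_config(n_trials = 240),
      agent_config("switching", switch_hazard = 1, block_len = 1L,
                   p_hit_attended = 0.5, p_hit_unattended = 0.5, p_cr = 0.5),
      seed = 13, session_id = "fx_null"),
    stop("unknown fixture ", name))
  .fx[[name]]
}

default_grid <- function() bin_grid("sample_on", c(-0.7, 1.9))

# pre-cue trials of a session subsampled to first k per cue location,
# plus the binned rate tensor
precue_rates <- function(session, k = 20, grid = default_grid()) {
  pre <- session$trials[session$trials$trial_type == "pre_cue", ]
  pre_k <- subsample_first_k(pre, pre$cue_location, k = k)
  list(trials = pre_k,
       rates = bin_firing_rates(session$spikes, pre_k, grid))
}
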