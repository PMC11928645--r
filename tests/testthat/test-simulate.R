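test_that("population class counts follow largest-remainder rounding", {
  pop <- make_population(100, c(location_only = 0.29, color_only = 0.04,
                                both = 0.23, untuned = 0.44), seed = 1)
  cls <- vapply(pop, `[[`, "", "class")
  expect_equal(unname(table(factor(cls, c("location_only", "color_only",
                                          "both", "untuned")))),
               as.table(c(29L, 4L, 23L, 44L)), ignore_attr = TRUE)
  all_loc <- make_population(10, c(location_only = 1, color_only = 0,
                                   both = 0, untuned = 0), seed = 1)
  expect_true(all(vapply(all_loc, `[[`, "", "class") == "location_only"))
  expect_error(make_population(10, c(location_only = 0.5, color_only = 0,
                                     both = 0, untuned = 0.4)),
               "sum to 1")
})

test_that("population generation is seed-deterministic", {
  p1 <- make_population(15, seed = 42)
  p2 <- make_population(15, seed = 42)
  p3 <- make_population(15, seed = 43)
  expect_identical(p1, p2)
  expect_false(identical(vapply(p1, `[[`, 0, "baseline_hz"),
                         vapply(p3, `[[`, 0, "baseline_hz")))
})

test_that("trial tables have locked sample onset and balanced conditions", {
  for (fx in c("fixed", "switch")) {
    tr <- fixture(fx)$trials
    expect_equal(unique(tr$sample_on - 2.0), 0.7)  # 0.7 s after initiation
    # per (type, cue loc, change/no-change) counts differ by <= 1
    cell <- table(tr$trial_type, tr$cue_location,
                  tr$change_location != "none")
    pre <- cell["pre_cue", c("top", "middle", "bottom"), ]
    expect_lte(max(pre) - min(pre), 1)
    nc_chg <- cell["no_cue", "none", "TRUE"]
    expect_equal(sum(tr$trial_type == "no_cue" &
                       tr$change_location != "none"),
                 sum(tr$trial_type == "no_cue") / 2)
    expect_equal(sum(tr$trial_type == "pre_cue" &
                       tr$change_location != "none"),
                 sum(tr$trial_type == "pre_cue") / 2)
    # pre-cue changes only at the cued location
    pc <- tr[tr$trial_type == "pre_cue" & tr$change_location != "none", ]
    expect_true(all(pc$change_location == pc$cue_location))
    # change iff exactly one compare color differs
    ndiff <- (tr$sample_color_top != tr$compare_color_top) +
      (tr$sample_color_middle != tr$compare_color_middle) +
      (tr$sample_color_bottom != tr$compare_color_bottom)
    expect_true(all((ndiff == 1) == (tr$change_location != "none")))
  }
})

test_that("cue locations never repeat more than twice consecutively", {
  for (seed in c(1, 5, 9)) {
    s <- simulate_session(make_population(1, seed = 1),
                          protocol_config(n_trials = 300),
                          agent_config("fixed", fixed_location = "top"),
                          seed = seed)
    cues <- s$trials$cue_location[s$trials$trial_type == "pre_cue"]
    runs <- rle(cues)
    expect_lte(max(runs$lengths), 2)
  }
})

test_that("spike trains respect timing invariants", {
  s <- fixture("fixed")
  sp <- s$spikes
  expect_true(all(sp$spike_time_s >= 0))
  expect_true(all(sp$spike_time_s <= s$trials$choice_on[1]))
  key <- interaction(sp$unit_id, sp$trial_id, drop = TRUE)
  incr <- tapply(sp$spike_time_s, key, function(v) all(diff(v) > 0))
  expect_true(all(unlist(incr)))
})

test_that("an untuned unit fires at its baseline rate (Poisson, Fano ~ 1)", {
  pop <- structure(list(unit_spec("u1", "untuned", baseline_hz = 10)),
                   class = "unit_population")
  s <- simulate_session(pop, protocol_config(n_trials = 1000),
                        agent_config("fixed", fixed_location = "top"),
                        seed = 3)
  dur <- s$trials$choice_on[1]
  n <- table(factor(s$spikes$trial_id, levels = s$trials$trial_id))
  rate <- as.numeric(n) / dur
  se <- sd(rate) / sqrt(length(rate))
  expect_lt(abs(mean(rate) - 10), 3 * se)
  # Fano factor of ITI spike counts (constant-rate epoch)
  iti_n <- table(factor(s$spikes$trial_id[s$spikes$spike_time_s < 2],
                        levels = s$trials$trial_id))
  fano <- var(as.numeric(iti_n)) / mean(as.numeric(iti_n))
  expect_lt(abs(fano - 1), 0.15)
})

test_that("a deterministic fixed-top agent produces the expected outcomes", {
  tr <- fixture("fixed")$trials
  nc <- tr[tr$trial_type == "no_cue", ]
  top <- nc[nc$change_location == "top", ]
  oth <- nc[nc$change_location %in% c("middle", "bottom"), ]
  expect_true(all(top$outcome == "hit"))
  expect_true(all(top$response_location == "top"))
  expect_true(all(oth$outcome == "miss"))
  expect_true(all(oth$response_location == "center"))
  expect_true(all(nc$outcome[nc$change_location == "none"] ==
                    "correct_rejection"))
})

test_that("simulation is reproducible from its master seed", {
  pop <- make_population(4, seed = 1)
  a <- simulate_session(pop, protocol_config(n_trials = 60),
                        agent_config("switching"), seed = 21)
  b <- simulate_session(pop, protocol_config(n_trials = 60),
                        agent_config("switching"), seed = 21)
  expect_identical(a$trials, b$trials)
  expect_identical(a$spikes, b$spikes)
  c2 <- simulate_session(pop, protocol_config(n_trials = 60),
                         agent_config("switching"), seed = 22)
  expect_false(identical(a$spikes, c2$spikes))
})

test_that("protocol invariants are enforced", {
  expect_error(protocol_config(cue_dur_s = 0.3), "time-locked")
  expect_error(protocol_config(sample_dur_s = -1), "positive")
  expect_error(simulate_session(make_population(1, seed = 1),
                                protocol_config(n_trials = 0)),
               "n_trials")
  expect_error(agent_config("fixed"), "fixed_location")
  expect_error(agent_config("switching", p_cr = 1.2), "\\[0, 1\\]")
})
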