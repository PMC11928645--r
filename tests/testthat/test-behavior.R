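# hand-built minimal no-cue trial table
toy_trials <- function(change_loc, outcome, trial_type = "no_cue") {
  n <- length(change_loc)
  tt <- data.frame(trial_id = seq_len(n), session_id = "toy",
                   trial_type = trial_type, cue_location = "none",
                   change_location = change_loc,
                   outcome = outcome, completed = TRUE)
  tt$response_location <- ifelse(outcome == "hit", change_loc, "center")
  class(tt) <- c("trial_table", "data.frame")
  tt
}

test_that("session performance: rates, conservation, undefined flags", {
  tr <- fixture("fixed")$trials
  perf <- session_performance(tr)
  nc <- perf[perf$trial_type == "no_cue", ]
  expect_equal(nc$hit_rate[nc$location == "top"], 100)
  expect_equal(nc$hit_rate[nc$location %in% c("middle", "bottom")], c(0, 0))
  expect_equal(nc$cr_rate, rep(100, 3))
  # hits + misses account for every change trial per location
  for (loc in c("top", "middle", "bottom")) {
    n_chg <- sum(tr$trial_type == "no_cue" & tr$change_location == loc)
    expect_equal(nc$n_hit[nc$location == loc] + nc$n_miss[nc$location == loc],
                 n_chg)
  }
  # zero denominator reports NA, not 0
  toy <- toy_trials(c("top", "top"), c("hit", "miss"))
  p <- session_performance(toy)
  expect_true(is.na(p$hit_rate[p$location == "middle"]))
  expect_true(is.na(p$cr_rate[1]))
})

test_that("block labels follow descending hit rate with display-order ties", {
  # one block, strict ordering {top 3/3, middle 1/3, bottom 0/3}
  tr <- toy_trials(rep(c("top", "middle", "bottom"), each = 3),
                   c("hit", "hit", "hit", "hit", "miss", "miss",
                     "miss", "miss", "miss"))
  bl <- block_preference(tr, n_blocks = 1)
  expect_equal(bl$label[bl$location == "top"], "preferred")
  expect_equal(bl$label[bl$location == "middle"], "intermediate")
  expect_equal(bl$label[bl$location == "bottom"], "least")
  # three-way tie resolves top > middle > bottom
  tie <- toy_trials(rep(c("top", "middle", "bottom"), each = 2),
                    rep(c("hit", "miss"), 3))
  bt <- block_preference(tie, n_blocks = 1)
  expect_equal(bt$label, c("preferred", "intermediate", "least"))
})

test_that("blocks partition completed trials with sizes differing by <= 1", {
  tr <- fixture("switch")$trials
  for (nb in c(3, 5, 7)) {
    done <- tr[tr$completed, ]
    sizes <- pevdecode:::largest_remainder(nrow(done), rep(1 / nb, nb))
    expect_equal(sum(sizes), nrow(done))
    expect_lte(max(sizes) - min(sizes), 1)
    bl <- block_preference(tr, n_blocks = nb)
    expect_equal(nrow(bl), nb * 3)
    # each block assigns all three labels exactly once
    for (b in seq_len(nb))
      expect_setequal(bl$label[bl$block == b],
                      c("preferred", "intermediate", "least"))
  }
})

test_that("session preference counts blocks and breaks ties by display order", {
  mk_blocks <- function(pref_by_block) {
    do.call(rbind, lapply(seq_along(pref_by_block), function(b) {
      locs <- c("top", "middle", "bottom")
      lab <- rep("intermediate", 3)
      lab[locs == pref_by_block[b]] <- "preferred"
      lab[which(lab == "intermediate")[2]] <- "least"
      data.frame(block = b, location = locs, hit_rate = NA, label = lab)
    }))
  }
  r <- session_preference(mk_blocks(c("top", "top", "top", "middle",
                                      "bottom")))
  expect_equal(r$preferred, "top")
  expect_equal(unname(r$counts), c(3, 1, 1))
  # tie 2-2-1 resolves to top
  r2 <- session_preference(mk_blocks(c("top", "top", "middle", "middle",
                                       "bottom")))
  expect_equal(r2$preferred, "top")
  # middle beats bottom on a middle/bottom tie
  r3 <- session_preference(mk_blocks(c("middle", "bottom")))
  expect_equal(r3$ordered, c("middle", "bottom", "top"))
})

test_that("dataset fractions: fixed agent concentrates, uniform agent spreads", {
  # full-length session so every block holds change trials at each location
  full <- simulate_session(structure(list(), class = "unit_population"),
                           protocol_config(n_trials = 850),
                           agent_config("fixed", fixed_location = "top",
                                        p_hit_attended = 1,
                                        p_hit_unattended = 0, p_cr = 1),
                           seed = 19)
  fixed <- preference_fractions(list(full$trials))
  expect_true(all(fixed$fractions[, "top"] >= 0.9))
  expect_true(fixed$stable)
  expect_equal(unname(rowSums(fixed$fractions)), rep(1, 8))
  # pooled uniform switching sessions approach 1/3 each
  set.seed(20)
  sessions <- lapply(1:6, function(i) simulate_session(
    structure(list(), class = "unit_population"),
    protocol_config(n_trials = 200),
    agent_config("switching", switch_hazard = 1, block_len = 1L,
                 p_hit_attended = 0.9, p_hit_unattended = 0.1),
    seed = 100 + i)$trials)
  unif <- preference_fractions(sessions, s_range = 5)
  expect_true(all(abs(unif$fractions - 1 / 3) < 0.25))
})

test_that("surrogate preference matches the switching agent's ground truth", {
  # slow switcher: when one attended location holds a strict majority of
  # no-cue trials, the surrogate recovers it (ties are unresolvable by
  # construction and are excluded)
  checked <- 0
  for (seed in c(31, 32, 33, 34, 35)) {
    s <- simulate_session(structure(list(), class = "unit_population"),
                          protocol_config(n_trials = 400),
                          agent_config("switching", switch_hazard = 0.3,
                                       block_len = 100L,
                                       p_hit_attended = 0.95,
                                       p_hit_unattended = 0.02),
                          seed = seed)
    nc <- s$trials[s$trials$trial_type == "no_cue", ]
    att <- table(nc$attended_location)
    if (max(att) / sum(att) < 0.55) next
    majority <- names(which.max(att))
    got <- session_preference(block_preference(s$trials))$preferred
    expect_equal(got, majority)
    checked <- checked + 1
  }
  expect_gte(checked, 2)
})

test_that("Kruskal-Wallis omnibus matches a textbook rank computation", {
  set.seed(40)
  for (i in 1:20) {
    g <- factor(rep(c("top", "middle", "bottom"), each = sample(4:9, 1)))
    y <- rnorm(length(g)) + as.integer(g) * runif(1, 0, 1)
    lt <- location_tests(y, g)
    n <- length(y); rk <- rank(y)
    h <- 12 / (n * (n + 1)) *
      sum(tapply(rk, g, function(r) length(r) * mean(r)^2)) - 3 * (n + 1)
    ties <- table(rk)
    h <- h / (1 - sum(ties^3 - ties) / (n^3 - n))
    expect_equal(lt$statistic, h, tolerance = 1e-10)
  }
})

test_that("location tests detect a superior location and flag degeneracy", {
  set.seed(41)
  g <- factor(rep(c("top", "middle", "bottom"), each = 10))
  y <- c(rnorm(10, 90, 3), rnorm(10, 40, 3), rnorm(10, 42, 3))
  lt <- location_tests(y, g)
  expect_lt(lt$p_value, 0.001)
  pw <- lt$pairwise
  tm <- pw[(pw$a == "top" & pw$b == "middle") |
             (pw$a == "middle" & pw$b == "top"), ]
  expect_lt(tm$p_adj, 0.05)
  deg <- location_tests(rep(50, 12), factor(rep(c("top", "middle",
                                                  "bottom"), 4)))
  expect_true(deg$degenerate)
  expect_equal(deg$p_value, 1)
  expect_error(location_tests(1:3, factor(c("a", "b", "c"))), "2 sessions")
})
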