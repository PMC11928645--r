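# small labeled tensor with controllable per-condition separation
sep_tensor <- function(n_units = 6, n_per = 30, nbins = 4, sep = 3,
                       seed = 10) {
  set.seed(seed)
  labs <- factor(rep(c("top", "middle", "bottom"), each = n_per))
  x <- array(rnorm(n_units * 3 * n_per * nbins),
             c(n_units, 3 * n_per, nbins))
  shift <- matrix(rnorm(n_units * 3), n_units, 3) * sep
  for (ci in 1:3) {
    idx <- which(as.integer(labs) == ci)
    x[, idx, ] <- x[, idx, ] + shift[, ci]
  }
  g <- bin_grid("sample_on", c(0, 0.2 * nbins), bin_width_s = 0.2,
                step_s = 0.2)
  list(rates = structure(x, unit_ids = sprintf("u%d", 1:n_units),
                         trial_ids = seq_along(labs), grid = g,
                         class = c("rate_tensor", "array")),
       labels = labs)
}

test_that("pseudo-trial sets have the documented shape and balance", {
  st <- sep_tensor()
  ps <- build_pseudo_trials(st$rates, st$labels, n_per_condition = 40,
                            seed = 1)
  expect_equal(dim(ps$x), c(120, 6, 4))
  expect_equal(as.vector(table(ps$labels)), rep(40L, 3))
  one <- build_pseudo_trials(st$rates, st$labels, n_per_condition = 1,
                             seed = 1)
  expect_equal(dim(one$x)[1], 3)
  ps2 <- build_pseudo_trials(st$rates, st$labels, n_per_condition = 40,
                             seed = 1)
  expect_identical(ps$x, ps2$x)
  expect_error(build_pseudo_trials(st$rates, st$labels,
                                   n_per_condition = 40, replace = FALSE),
               "insufficient trials")
})

test_that("pseudo-trial values are resampled from the source trials", {
  st <- sep_tensor(n_units = 3, n_per = 20)
  ps <- build_pseudo_trials(st$rates, st$labels, n_per_condition = 15,
                            seed = 2)
  for (ci in seq_along(levels(st$labels))) {
    rows <- which(ps$labels == levels(st$labels)[ci])
    src <- which(st$labels == levels(st$labels)[ci])
    for (u in 1:3)
      expect_true(all(ps$x[rows, u, 1] %in% st$rates[u, src, 1]))
  }
})

test_that("per-bin z-scoring normalizes, flags degenerate bins, idempotent", {
  st <- sep_tensor()
  ps <- build_pseudo_trials(st$rates, st$labels, seed = 1)
  ps$x[, , 2] <- 7  # constant bin
  z <- zscore_per_bin(ps)
  expect_equal(mean(z$x[, , 1]), 0, tolerance = 1e-12)
  expect_equal(sd(as.vector(z$x[, , 1])), 1, tolerance = 1e-12)
  expect_true(z$degenerate[2])
  expect_true(all(z$x[, , 2] == 0))
  z2 <- zscore_per_bin(z)
  expect_equal(z2$x, z$x, tolerance = 1e-10)
  # per-unit variant normalizes each unit
  zu <- zscore_per_bin(ps, per_unit = TRUE)
  expect_equal(mean(zu$x[, 3, 1]), 0, tolerance = 1e-12)
  expect_equal(sd(zu$x[, 3, 1]), 1, tolerance = 1e-12)
})

test_that("a linearly separable population decodes at ceiling on the diagonal", {
  st <- sep_tensor(sep = 6)
  ps <- zscore_per_bin(build_pseudo_trials(st$rates, st$labels, seed = 3))
  dm <- decode_cross_temporal(ps, n_resamples = 20, seed = 4)
  expect_true(all(diag(dm$performance) > 0.95))
  expect_true(all(dm$performance >= 0 & dm$performance <= 1))
})

test_that("shuffled labels decode at chance and decoding is deterministic", {
  st <- sep_tensor(sep = 6)
  ps <- zscore_per_bin(build_pseudo_trials(st$rates, st$labels, seed = 3))
  null <- shuffled_baseline(ps, n_resamples = 40, seed = 5,
                            diagonal_only = TRUE)
  expect_lt(abs(mean(diag(null$performance)) - 1 / 3), 0.05)
  a <- decode_cross_temporal(ps, n_resamples = 10, seed = 6)
  b <- decode_cross_temporal(ps, n_resamples = 10, seed = 6)
  expect_identical(a$performance, b$performance)
  expect_error(decode_cross_temporal(ps, train_frac = 0.999),
               "invalid-config")
})

test_that("decoding accuracy grows with tuning separation", {
  acc <- vapply(c(0.2, 0.8, 3), function(sep) {
    st <- sep_tensor(sep = sep, nbins = 1, seed = 11)
    ps <- zscore_per_bin(build_pseudo_trials(st$rates, st$labels, seed = 3))
    dm <- decode_cross_temporal(ps, n_resamples = 25, seed = 4)
    mean(diag(dm$performance))
  }, numeric(1))
  expect_true(all(diff(acc) > 0))
})

test_that("flood-fill cluster labeling agrees with an igraph oracle", {
  skip_if_not_installed("igraph")
  set.seed(12)
  for (i in 1:20) {
    m <- matrix(runif(12 * 12) < 0.35, 12, 12)
    lab <- pevdecode:::label_clusters(m)
    # oracle: connected components of the 4-adjacency graph on TRUE cells
    cells <- which(m, arr.ind = TRUE)
    if (nrow(cells) == 0) {
      expect_equal(max(lab), 0)
      next
    }
    id <- seq_len(nrow(cells))
    edges <- c()
    for (a in id) for (b in id) {
      if (a < b && sum(abs(cells[a, ] - cells[b, ])) == 1)
        edges <- c(edges, a, b)
    }
    g <- igraph::make_graph(edges, n = nrow(cells), directed = FALSE)
    comp <- igraph::components(g)$membership
    ours <- lab[cells]
    # same partition: component labels map 1-1
    expect_equal(length(unique(ours)), length(unique(comp)))
    expect_true(all(tapply(comp, ours, function(v) length(unique(v))) == 1))
  }
})

test_that("cluster size filtering retains only regions exceeding the threshold", {
  nb <- 10
  mk <- function(perf_cells) {
    perf <- matrix(0.34, nb, nb)
    perf[perf_cells] <- 0.9
    res <- array(rep(perf, 30), c(nb, nb, 30))
    structure(list(performance = perf, spread = matrix(0, nb, nb),
                   resamples = res, bins = 1:nb, centers = 1:nb,
                   chance = 1 / 3, n_resamples = 30L, train_frac = 0.9,
                   shuffled = FALSE), class = "decoding_matrix")
  }
  null <- mk(matrix(FALSE, nb, nb))
  null$resamples <- array(rnorm(nb * nb * 30, 1 / 3, 0.02), c(nb, nb, 30))
  four <- cbind(2, 2:5)          # 4-cell line: removed at threshold 5
  six <- cbind(8, 3:8)           # 6-cell line: retained
  dm <- significance_map(mk(rbind(four, six)), null, min_cluster_bins = 5)
  expect_equal(length(dm$clusters), 1)
  expect_equal(dm$clusters[[1]]$size, 6)
  expect_true(all(dm$significant[six]))
  expect_false(any(dm$significant[four]))
  # a matched-size region of 5 does not *exceed* 5 and is removed
  dm5 <- significance_map(mk(cbind(4, 3:7)), null, min_cluster_bins = 5)
  expect_equal(length(dm5$clusters), 0)
})

test_that("a null session produces no significant decoding clusters", {
  s <- fixture("null")
  pr <- precue_rates(s, k = 20)
  nov <- select_nonoverlapping(default_grid())
  ps <- zscore_per_bin(build_pseudo_trials(pr$rates,
                                           pr$trials$cue_location, seed = 2))
  dm <- decode_cross_temporal(ps, n_resamples = 25, seed = 3, bins = nov)
  null <- shuffled_baseline(ps, n_resamples = 25, seed = 4, bins = nov)
  dm <- significance_map(dm, null)
  expect_equal(length(dm$clusters), 0)
  expect_false(any(dm$diag_significant))
})

test_that("transfer fractions sum to one and recover the attended location", {
  s <- fixture("fixed")
  pr <- precue_rates(s, k = 20)
  nov <- select_nonoverlapping(default_grid())
  ps <- zscore_per_bin(build_pseudo_trials(pr$rates,
                                           pr$trials$cue_location, seed = 5))
  nocue <- s$trials[s$trials$trial_type == "no_cue", ]
  rt_no <- bin_firing_rates(s$spikes, nocue, default_grid(),
                            unit_ids = attr(pr$rates, "unit_ids"))
  tp <- zscore_per_bin(build_pseudo_trials(rt_no,
                                           rep("no_cue", nrow(nocue)),
                                           n_per_condition = 40, seed = 6))
  tf <- transfer_decode(ps, tp, n_resamples = 8, seed = 7, bins = nov)
  expect_equal(unname(rowSums(tf$per_bin[, tf$classes])),
               rep(1, length(nov)), tolerance = 1e-9)
  expect_equal(sum(tf$overall), 1, tolerance = 1e-9)
  expect_equal(names(which.max(tf$overall)), "top")
  expect_error(transfer_decode(ps, zscore_per_bin(
    build_pseudo_trials(pr$rates[1:3, , , drop = FALSE] |>
                          structure(unit_ids = sprintf("u%d", 1:3),
                                    trial_ids = attr(pr$rates, "trial_ids"),
                                    grid = default_grid(),
                                    class = c("rate_tensor", "array")),
                        pr$trials$cue_location, seed = 1)), seed = 1),
    "different units")
})
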