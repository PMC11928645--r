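TRIAL_COLS <- c("trial_id", "session_id", "trial_type", "cue_location",
                "sample_color_top", "sample_color_middle",
                "sample_color_bottom", "compare_color_top",
                "compare_color_middle", "compare_color_bottom",
                "change_location", "cue_on", "cue_off", "sample_on",
                "sample_off", "compare_on", "choice_on", "completed",
                "attended_location", "response_location", "outcome")

#' Write a trial table to CSV
#'
#' One row per trial, event times as 6-decimal fixed point seconds.
#'
#' @param trials A `trial_table`.
#' @param path Output file.
#' @export
write_trial_table <- function(trials, path) {
  out <- trials[, intersect(TRIAL_COLS, names(trials))]
  for (cn in c("cue_on", "cue_off", "sample_on", "sample_off", "compare_on",
               "choice_on"))
    out[[cn]] <- sprintf("%.6f", out[[cn]])
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write spike data to CSV
#'
#' Columns `unit_id`, `trial_id`, `spike_time_s` (6-decimal seconds).
#'
#' @param spikes Spike data frame.
#' @param path Output file.
#' @export
write_spike_data <- function(spikes, path) {
  out <- data.frame(unit_id = spikes$unit_id, trial_id = spikes$trial_id,
                    spike_time_s = sprintf("%.6f", spikes$spike_time_s))
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read and validate trial and spike CSV files
#'
#' Parses the CSV schemas written by [write_trial_table()] and
#' [write_spike_data()], reporting schema violations with row numbers:
#' missing columns, unknown enum values, negative or non-increasing spike
#' times within a (unit, trial).
#'
#' @param trial_csv,spike_csv File paths.
#' @return List with `trials` (a `trial_table`) and `spikes`.
#' @export
read_tables <- function(trial_csv, spike_csv) {
  tr <- utils::read.csv(trial_csv, stringsAsFactors = FALSE)
  need <- c("trial_id", "session_id", "trial_type", "cue_location",
            "change_location", "sample_on", "choice_on", "outcome")
  miss <- setdiff(need, names(tr))
  if (length(miss) > 0)
    stop("parse error: trial table missing column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  bad_tt <- which(!tr$trial_type %in% c("pre_cue", "no_cue"))
  if (length(bad_tt) > 0)
    stop("parse error: unknown trial_type at row(s) ",
         paste(utils::head(bad_tt, 5), collapse = ", "), call. = FALSE)
  enum_loc <- c("top", "middle", "bottom", "none", "center")
  for (cn in intersect(c("cue_location", "change_location",
                         "response_location", "attended_location"),
                       names(tr))) {
    bad <- which(!tr[[cn]] %in% enum_loc)
    if (length(bad) > 0)
      stop("parse error: unknown ", cn, " at row(s) ",
           paste(utils::head(bad, 5), collapse = ", "), call. = FALSE)
  }
  if (!"completed" %in% names(tr)) tr$completed <- TRUE
  tr$completed <- as.logical(tr$completed)
  class(tr) <- c("trial_table", "data.frame")

  sp <- utils::read.csv(spike_csv, stringsAsFactors = FALSE)
  miss <- setdiff(c("unit_id", "trial_id", "spike_time_s"), names(sp))
  if (length(miss) > 0)
    stop("parse error: spike table missing column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  bad <- which(!is.finite(sp$spike_time_s) | sp$spike_time_s < 0)
  if (length(bad) > 0)
    stop("parse error: negative or non-numeric spike_time_s at row(s) ",
         paste(utils::head(bad, 5), collapse = ", "), call. = FALSE)
  ord_ok <- unlist(tapply(sp$spike_time_s,
                          interaction(sp$unit_id, sp$trial_id, drop = TRUE),
                          function(v) c(TRUE, diff(v) >= 0)), use.names = FALSE)
  if (!all(ord_ok))
    stop("parse error: spike times not sorted within unit/trial",
         call. = FALSE)
  list(trials = tr, spikes = sp)
}

#' Write the canonical synthetic fixture sessions
#'
#' Three small sessions used by tests and documentation: a switching-agent
#' session ("bird-1-like"), a fixed-top-agent session ("bird-2-like"), and
#' a null session (untuned units, no attentional modulation).
#'
#' @param out_dir Writable directory (created if absent).
#' @param seed Master seed.
#' @param n_trials,n_units Session size.
#' @return Invisibly, the named list of written file paths.
#' @export
generate_fixture_suite <- function(out_dir, seed = 0L, n_trials = 240L,
                                   n_units = 12L) {
  if (!dir.exists(out_dir))
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir))
    stop("I/O error: cannot create directory ", out_dir, call. = FALSE)
  proto <- protocol_config(n_trials = n_trials)
  specs <- list(
    bird1 = list(pop = make_population(n_units, seed = substream_seed(seed, "pop1")),
                 agent = agent_config("switching", switch_hazard = 0.8,
                                      block_len = 20L)),
    bird2 = list(pop = make_population(n_units, seed = substream_seed(seed, "pop2")),
                 agent = agent_config("fixed", fixed_location = "top",
                                      p_hit_attended = 1, p_hit_unattended = 0,
                                      p_cr = 1)),
    null = list(pop = make_population(n_units,
                                      class_fractions = c(location_only = 0,
                                                          color_only = 0,
                                                          both = 0, untuned = 1),
                                      seed = substream_seed(seed, "pop0"),
                                      attn_gain = 1),
                agent = agent_config("switching", switch_hazard = 1,
                                     block_len = 1L, p_hit_attended = 0.5,
                                     p_hit_unattended = 0.5, p_cr = 0.5)))
  paths <- list()
  for (nm in names(specs)) {
    s <- simulate_session(specs[[nm]]$pop, proto, specs[[nm]]$agent,
                          seed = substream_seed(seed, nm),
                          session_id = nm)
    tp <- file.path(out_dir, paste0(nm, "_trials.csv"))
    sp <- file.path(out_dir, paste0(nm, "_spikes.csv"))
    write_trial_table(s$trials, tp)
    write_spike_data(s$spikes, sp)
    paths[[nm]] <- c(trials = tp, spikes = sp)
  }
  invisible(paths)
}

#' Pipeline run configuration
#'
#' Collects paths, bin-grid parameters, stage toggles and per-stage seeds
#' for [run_pipeline()]. Every stochastic stage has an explicit seed,
#' recorded in the run manifest.
#'
#' @param out_dir Output directory for artifacts and the manifest.
#' @param trial_csv,spike_csv Input files; when `NULL` a session is
#'   simulated from `population`/`protocol`/`agent`.
#' @param population,protocol,agent Simulation configs (used when no input
#'   files are given).
#' @param grid A [bin_grid()].
#' @param stages Character subset of
#'   `c("pev", "shift", "decode", "transfer", "behavior")`.
#' @param k First-k trials per condition for subsampling.
#' @param n_perm Label permutations for the PEV null band.
#' @param n_resamples Decoder resamples.
#' @param train_frac Decoder training fraction.
#' @param n_per_condition Pseudo-trials per condition.
#' @param min_cluster_bins Decoder cluster threshold.
#' @param shift_location Location analyzed by the shift stage.
#' @param seed Master seed.
#' @return A list of class `run_config`.
#' @export
run_config <- function(out_dir, trial_csv = NULL, spike_csv = NULL,
                       population = NULL, protocol = protocol_config(),
                       agent = agent_config("fixed", fixed_location = "top"),
                       grid = bin_grid(), stages = c("pev", "shift", "decode",
                                                     "transfer", "behavior"),
                       k = 20L, n_perm = 200L, n_resamples = 100L,
                       train_frac = 0.9, n_per_condition = 40L,
                       min_cluster_bins = 5L, shift_location = "top",
                       seed = 1L) {
  stages <- match.arg(stages, several.ok = TRUE)
  structure(list(out_dir = out_dir, trial_csv = trial_csv,
                 spike_csv = spike_csv, population = population,
                 protocol = protocol, agent = agent, grid = grid,
                 stages = stages, k = k, n_perm = n_perm,
                 n_resamples = n_resamples, train_frac = train_frac,
                 n_per_condition = n_per_condition,
                 min_cluster_bins = min_cluster_bins,
                 shift_location = shift_location, seed = seed),
            class = "run_config")
}

#' Run the full analysis pipeline
#'
#' Simulates or loads a session, applies inclusion filters and first-k
#' subsampling, bins firing rates, and executes the enabled analysis
#' stages, writing every artifact as CSV/JSON plus a machine-readable run
#' manifest (config snapshot, seeds, artifact checksums).
#'
#' @param config A [run_config()].
#' @return The manifest (list), invisibly; artifacts are written to
#'   `config$out_dir`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  artifacts <- character(0)
  stage <- "load"
  manifest <- list(package_version = as.character(utils::packageVersion("pevdecode")),
                   seed = config$seed, stages = config$stages,
                   parameters = list(k = config$k, n_perm = config$n_perm,
                                     n_resamples = config$n_resamples,
                                     train_frac = config$train_frac,
                                     n_per_condition = config$n_per_condition,
                                     min_cluster_bins = config$min_cluster_bins,
                                     bin_width_s = config$grid$bin_width_s,
                                     step_s = config$grid$step_s,
                                     classifier = "linear SVM (one-vs-one)"))
  res <- tryCatch({
    if (!is.null(config$trial_csv)) {
      tabs <- read_tables(config$trial_csv, config$spike_csv)
    } else {
      stage <- "simulate"
      s <- simulate_session(config$population, config$protocol, config$agent,
                            seed = substream_seed(config$seed, "session"))
      tabs <- list(trials = s$trials, spikes = s$spikes)
      write_trial_table(s$trials, file.path(config$out_dir, "trials.csv"))
      write_spike_data(s$spikes, file.path(config$out_dir, "spikes.csv"))
      artifacts <- c(artifacts, file.path(config$out_dir,
                                          c("trials.csv", "spikes.csv")))
    }
    trials <- tabs$trials; spikes <- tabs$spikes
    grid <- config$grid
    nov <- select_nonoverlapping(grid)

    stage <- "filter"
    filt <- apply_inclusion_filters(spikes, trials)
    spikes <- spikes[spikes$unit_id %in% filt$unit_ids &
                       spikes$trial_id %in% filt$trial_ids, ]
    trials_f <- trials[trials$trial_id %in% filt$trial_ids, ]

    pre <- trials_f[trials_f$trial_type == "pre_cue", ]
    pre20 <- subsample_first_k(pre, pre$cue_location, k = config$k)
    rt_pre <- bin_firing_rates(spikes, pre20, grid,
                               unit_ids = filt$unit_ids)

    cls <- NULL
    if ("pev" %in% config$stages) {
      stage <- "pev"
      series <- pev_timecourse(rt_pre, pre20$cue_location,
                               n_perm = config$n_perm,
                               seed = substream_seed(config$seed, "perm"))
      summ <- population_summary(series)
      p <- file.path(config$out_dir, "pev_location.csv")
      utils::write.csv(
        data.frame(unit_id = rep(series$unit_ids, ncol(series$pev)),
                   bin_center_s = rep(series$centers, each = nrow(series$pev)),
                   statistic = "omega2_location",
                   value = as.vector(series$pev),
                   significant = as.vector(series$significant)),
        p, row.names = FALSE)
      utils::write.csv(summ, file.path(config$out_dir, "pev_summary.csv"),
                       row.names = FALSE)
      artifacts <- c(artifacts, p, file.path(config$out_dir, "pev_summary.csv"))
      cls <- classify_units(
        rt_pre, pre20$cue_location,
        pre20[[paste0("sample_color_", config$shift_location)]])
    }

    if ("shift" %in% config$stages) {
      stage <- "shift"
      sh <- color_shift_analysis(trials_f, spikes, config$shift_location,
                                 grid, k = config$k,
                                 unit_ids = filt$unit_ids)
      long <- data.frame(
        unit_id = rep(filt$unit_ids, ncol(sh$gain) * 3),
        bin_center_s = rep(rep(sh$centers, each = nrow(sh$gain)), 3),
        statistic = rep(c("gain", "loss", "overall"),
                        each = length(sh$gain)),
        value = c(as.vector(sh$gain), as.vector(sh$loss),
                  as.vector(sh$overall)))
      p <- file.path(config$out_dir, "shift_table.csv")
      utils::write.csv(long, p, row.names = FALSE)
      artifacts <- c(artifacts, p)
    }

    if (any(c("decode", "transfer") %in% config$stages)) {
      stage <- "pseudo"
      if (is.null(cls))
        cls <- classify_units(
          rt_pre, pre20$cue_location,
          pre20[[paste0("sample_color_", config$shift_location)]])
      loc_units <- names(cls$class)[cls$class %in% c("location_only", "both")]
      if (length(loc_units) < 2) loc_units <- filt$unit_ids
      rt_dec <- bin_firing_rates(spikes, pre20, grid, unit_ids = loc_units)
      pseudo <- build_pseudo_trials(rt_dec, pre20$cue_location,
                                    n_per_condition = config$n_per_condition,
                                    seed = substream_seed(config$seed, "pseudo"))
      pseudo <- zscore_per_bin(pseudo)
    }

    if ("decode" %in% config$stages) {
      stage <- "decode"
      dm <- decode_cross_temporal(pseudo, train_frac = config$train_frac,
                                  n_resamples = config$n_resamples,
                                  seed = substream_seed(config$seed, "decode"),
                                  bins = nov)
      null <- shuffled_baseline(pseudo, n_resamples = config$n_resamples,
                                seed = substream_seed(config$seed, "null"),
                                train_frac = config$train_frac, bins = nov)
      dm <- significance_map(dm, null,
                             min_cluster_bins = config$min_cluster_bins)
      p <- file.path(config$out_dir, "decoding_matrix.csv")
      utils::write.csv(as.data.frame(dm$performance), p, row.names = FALSE)
      side <- list(bins = dm$bins, centers = dm$centers,
                   n_resamples = dm$n_resamples, train_frac = dm$train_frac,
                   classifier = dm$classifier, chance = dm$chance,
                   n_clusters = length(dm$clusters),
                   seed = substream_seed(config$seed, "decode"))
      jsonlite::write_json(side, file.path(config$out_dir, "decoding_meta.json"),
                           auto_unbox = TRUE, digits = NA)
      artifacts <- c(artifacts, p,
                     file.path(config$out_dir, "decoding_meta.json"))
    }

    if ("transfer" %in% config$stages) {
      stage <- "transfer"
      nocue <- trials_f[trials_f$trial_type == "no_cue", ]
      rt_no <- bin_firing_rates(spikes, nocue, grid,
                                unit_ids = pseudo$unit_ids)
      test_pseudo <- build_pseudo_trials(
        rt_no, rep("no_cue", nrow(nocue)), n_per_condition = 40L,
        seed = substream_seed(config$seed, "pseudo_nocue"))
      test_pseudo <- zscore_per_bin(test_pseudo)
      tf <- transfer_decode(pseudo, test_pseudo,
                            n_resamples = max(20L, config$n_resamples %/% 5L),
                            train_frac = config$train_frac,
                            seed = substream_seed(config$seed, "transfer"),
                            bins = nov)
      p <- file.path(config$out_dir, "transfer_result.csv")
      utils::write.csv(tf$per_bin, p, row.names = FALSE)
      artifacts <- c(artifacts, p)
    }

    if ("behavior" %in% config$stages) {
      stage <- "behavior"
      perf <- session_performance(trials)
      bl <- block_preference(trials)
      pref <- preference_fractions(list(trials))
      utils::write.csv(perf, file.path(config$out_dir, "performance.csv"),
                       row.names = FALSE)
      utils::write.csv(bl, file.path(config$out_dir, "block_preference.csv"),
                       row.names = FALSE)
      jsonlite::write_json(
        list(fractions = as.data.frame(pref$fractions),
             modal = as.list(pref$modal), stable = pref$stable),
        file.path(config$out_dir, "preference.json"), auto_unbox = TRUE,
        digits = NA)
      artifacts <- c(artifacts,
                     file.path(config$out_dir, c("performance.csv",
                                                 "block_preference.csv",
                                                 "preference.json")))
    }
    TRUE
  }, error = function(e) {
    stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
         call. = FALSE)
  })
  manifest$artifacts <- lapply(stats::setNames(artifacts, basename(artifacts)),
                               function(p) unname(tools::md5sum(p)))
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}
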