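#' The 2x2 simulated experiment and its behaviour metrics
#'
#' Reproduces the evaluation protocol: a within-subjects 2x2 design
#' crossing speed (60, 120 km/h) with search set size (6, 9 items),
#' 24 trials per condition (12 target-present, 12 foil, shuffled), metric
#' extraction from trial traces, within- then across-participant
#' aggregation, and model-to-human fit indices.
#'
#' @name experiment
NULL

#' The four experimental conditions
#' @return Tibble crossing `speed_kmh` in \{60, 120\} with `n_items` in
#'   \{6, 9\}.
#' @export
condition_grid <- function() {
  tidyr::expand_grid(speed_kmh = c(60, 120), n_items = c(6L, 9L))
}

metric_names <- function() {
  c("trial_time", "offset_sd", "n_lane_deviations",
    "n_incar_glances", "mean_incar_glance_duration")
}

#' Partition a trial timeline into road and in-car glances
#'
#' An in-car glance spans from the start of the switch toward the display
#' to the start of the switch back to the road (the eyes are off the road
#' for the whole span, including both travel times on the outbound side).
#' The timeline starts as a road span (attention begins on the road);
#' span durations partition the trial time exactly.
#'
#' @param trace A `trial_trace` from [run_trial()].
#' @return Tibble with one row per maximal span: `type` (`"road"` or
#'   `"incar"`), `t_start`, `t_end`, `duration`.
#' @export
extract_glances <- function(trace) {
  ev <- trace$events
  breaks <- ev$t_start[ev$kind == "switch"]
  types_to <- ev$to_focus[ev$kind == "switch"]
  t_end <- trace$trial_time
  starts <- c(0, breaks)
  ends <- c(breaks, t_end)
  types <- c("road", ifelse(types_to == "search", "incar", "road"))
  keep <- ends - starts > 1e-12
  tibble::tibble(type = types[keep], t_start = starts[keep],
                 t_end = ends[keep], duration = (ends - starts)[keep])
}

#' Behaviour metrics of one trial
#'
#' Computes the five distraction metrics from a trial trace: trial time;
#' the standard deviation of the lateral offset (sampled at the end of
#' every driving sub-step, attended or blind); the number of lane
#' deviations, counted once at the onset of each maximal excursion beyond
#' the lane half-width; and the number and mean duration of in-car glances.
#'
#' @param trace A `trial_trace`.
#' @param lane_half_bound_m Lane-deviation threshold in metres; defaults to
#'   half the standard 3.5 m lane.
#' @return One-row tibble of `trial_metrics`.
#' @export
compute_metrics <- function(trace, lane_half_bound_m = 1.75) {
  off <- trace$offsets$offset_m
  out <- abs(off) > lane_half_bound_m
  onsets <- sum(out & !c(FALSE, out[-length(out)]))
  gl <- extract_glances(trace)
  incar <- gl[gl$type == "incar", ]
  tibble::tibble(
    trial_time = trace$trial_time,
    offset_sd = if (length(off) > 1) sd(off) else 0,
    n_lane_deviations = onsets,
    n_incar_glances = nrow(incar),
    mean_incar_glance_duration = if (nrow(incar) > 0) mean(incar$duration)
                                 else NA_real_,
    trial_type = if (trace$target_present) "target" else "foil",
    completed = trace$completed,
    aborted = trace$aborted
  )
}

#' Run the trial protocol of one condition
#'
#' For each simulated participant (a distinct evaluation seed over the
#' shared trained policies) runs 24 trials --- 12 target-present and
#' 12 foil screens in shuffled order --- and returns per-trial metrics.
#'
#' @param policies A trained [train_policies()] object.
#' @param n_participants Number of simulated participants.
#' @param n_trials Trials per participant (half target, half foil).
#' @param seed Master seed; the output table is reproducible given
#'   (policies, seed).
#' @return Tibble of per-trial metrics with `participant`, `trial`,
#'   `speed_kmh`, `n_items` columns.
#' @export
run_condition <- function(policies, n_participants = 12, n_trials = 24,
                          seed = 1) {
  if (is.null(policies$sup_q)) {
    abort("`policies` must include a trained supervisory policy")
  }
  if (n_trials %% 2 != 0) abort("`n_trials` must be even (half target, half foil)")
  purrr::map_dfr(seq_len(n_participants), function(p) {
    set.seed(derive_seed(seed, p))
    types <- sample(rep(c(TRUE, FALSE), each = n_trials / 2))
    purrr::map_dfr(seq_len(n_trials), function(tr) {
      trace <- run_trial_engine(policies, target_present = types[tr])$trace
      m <- compute_metrics(trace, policies$config$driving$lane_half_bound_m)
      dplyr::mutate(m, participant = p, trial = tr,
                    speed_kmh = policies$config$speed_kmh,
                    n_items = policies$config$n_items,
                    .before = 1)
    })
  })
}

#' Train and simulate the full 2x2 experiment
#'
#' Trains one set of policies per condition (driving and search learners
#' are condition-specific, as is the supervisory model) and runs the trial
#' protocol for every condition.
#'
#' @param n_participants Simulated participants per condition.
#' @param n_trials Trials per participant.
#' @param profile Training-effort profile.
#' @param seed Master seed.
#' @param conditions Condition table, defaults to [condition_grid()].
#' @param progress Emit per-condition progress messages.
#' @return List with `metrics` (per-trial tibble over all conditions) and
#'   `policies` (named list of trained policy bundles).
#' @export
run_experiment <- function(n_participants = 4, n_trials = 24,
                           profile = "fast", seed = 1,
                           conditions = condition_grid(),
                           progress = FALSE) {
  pol <- list()
  metrics <- purrr::pmap_dfr(conditions, function(speed_kmh, n_items) {
    key <- sprintf("s%d_i%d", speed_kmh, n_items)
    if (progress) message("training condition ", key)
    p <- train_policies(speed_kmh, n_items, profile = profile,
                        seed = derive_seed(seed, speed_kmh + n_items))
    pol[[key]] <<- p
    if (progress) message("simulating condition ", key)
    run_condition(p, n_participants, n_trials,
                  seed = derive_seed(seed, 1000 + speed_kmh + n_items))
  })
  list(metrics = metrics, policies = pol)
}

#' Aggregate per-trial metrics within and then across participants
#'
#' Metrics are first averaged within participant (per condition and trial
#' type), then across participants; the across-participant mean and
#' standard error (n = participants) are reported per cell.
#'
#' @param metrics Per-trial tibble from [run_condition()] /
#'   [run_experiment()].
#' @param by_trial_type Keep target and foil cells separate (8 cells);
#'   `FALSE` pools them (4 cells).
#' @return Long summary tibble (`metric`, `mean`, `se`, `n`) of class
#'   `multitask_summary`.
#' @export
aggregate_metrics <- function(metrics, by_trial_type = TRUE) {
  grp <- c("speed_kmh", "n_items", if (by_trial_type) "trial_type")
  long <- tidyr::pivot_longer(metrics, cols = dplyr::all_of(metric_names()),
                              names_to = "metric", values_to = "value")
  out <- long |>
    dplyr::group_by(dplyr::across(dplyr::all_of(c(grp, "metric", "participant")))) |>
    dplyr::summarise(value = mean(.data$value, na.rm = TRUE), .groups = "drop") |>
    dplyr::group_by(dplyr::across(dplyr::all_of(c(grp, "metric")))) |>
    dplyr::summarise(mean = mean(.data$value),
                     se = sd(.data$value) / sqrt(dplyr::n()),
                     n = dplyr::n(), .groups = "drop")
  class(out) <- c("multitask_summary", class(out))
  out
}

#' Fit indices comparing model predictions to human aggregates
#'
#' For each behaviour metric, compares the model's cell means (condition by
#' trial type) with human cell means: mean absolute error across cells;
#' that error relative to the human mean; the error in units of the human
#' across-participant SD; and the R-squared of an ordinary least-squares
#' regression of the human observations on the model predictions.
#'
#' @param model_summary A [aggregate_metrics()] summary of simulated data.
#' @param human_summary Tibble of human cell aggregates with columns
#'   `speed_kmh`, `n_items`, `trial_type`, `metric`, `mean`, `sd` (see
#'   [read_human_summary()]).
#' @return Tibble with one row per metric: `absolute_error`,
#'   `relative_error`, `error_in_sd_units`, `r_squared`.
#' @export
compute_fit_indices <- function(model_summary, human_summary) {
  keys <- intersect(c("speed_kmh", "n_items", "trial_type"),
                    intersect(names(model_summary), names(human_summary)))
  joined <- dplyr::inner_join(
    dplyr::select(model_summary, dplyr::all_of(c(keys, "metric")),
                  model = "mean"),
    dplyr::select(human_summary, dplyr::all_of(c(keys, "metric")),
                  human = "mean", human_sd = "sd"),
    by = c(keys, "metric"))
  n_cells_model <- nrow(dplyr::distinct(model_summary,
                                        dplyr::across(dplyr::all_of(keys))))
  n_cells_joined <- nrow(dplyr::distinct(joined,
                                         dplyr::across(dplyr::all_of(keys))))
  if (n_cells_joined < n_cells_model) {
    abort("human summary does not cover all model condition cells")
  }
  joined |>
    dplyr::group_by(.data$metric) |>
    dplyr::summarise(
      absolute_error = mean(abs(.data$model - .data$human)),
      relative_error = mean(abs(.data$model - .data$human)) /
        mean(.data$human),
      error_in_sd_units = mean(abs(.data$model - .data$human)) /
        mean(.data$human_sd),
      r_squared = summary(lm(human ~ model,
                             data = dplyr::pick(dplyr::everything())))$r.squared,
      n_cells = dplyr::n())
}

#' Read a per-participant human summary file
#'
#' Expects the plain-CSV schema `speed_kmh, n_items, trial_type, metric,
#' participant, value` (one row per participant, condition cell and
#' metric) and reduces it to cell aggregates (mean, across-participant SD).
#' The file bundled with the package
#' (`extdata/human_summary_synthetic.csv`) is a synthetic stand-in
#' generated by [synthetic_human_summary()], not real participant data.
#'
#' @param path CSV path; defaults to the bundled synthetic file.
#' @param by_trial_type Keep trial types separate; `FALSE` pools them.
#' @return Cell-aggregate tibble suitable for [compute_fit_indices()].
#' @export
read_human_summary <- function(path = system.file("extdata",
                                                  "human_summary_synthetic.csv",
                                                  package = "multidrive"),
                               by_trial_type = TRUE) {
  df <- tibble::as_tibble(utils::read.csv(path))
  need <- c("speed_kmh", "n_items", "trial_type", "metric", "participant", "value")
  if (!all(need %in% names(df))) {
    abort(paste("human summary must have columns:", paste(need, collapse = ", ")))
  }
  grp <- c("speed_kmh", "n_items", if (by_trial_type) "trial_type")
  if (!by_trial_type) {
    df <- df |>
      dplyr::group_by(dplyr::across(dplyr::all_of(c(grp, "metric", "participant")))) |>
      dplyr::summarise(value = mean(.data$value), .groups = "drop")
  }
  df |>
    dplyr::group_by(dplyr::across(dplyr::all_of(c(grp, "metric")))) |>
    dplyr::summarise(mean = mean(.data$value), sd = sd(.data$value),
                     n = dplyr::n(), .groups = "drop")
}

#' Generate a synthetic per-participant human summary
#'
#' A stand-in for a real human dataset, for exercising the fit-index
#' machinery. Cell means follow additive condition effects of the size and
#' sign typical of dual-task driving studies (longer trials, more and
#' longer in-car glances with more search items; greater lateral variation
#' at higher speed; foil trials longer than target-present ones), with
#' Gaussian between-participant variation around each cell mean. It is not
#' human data and carries no information about any real sample beyond
#' these effect directions.
#'
#' @param n_participants Simulated sample size.
#' @param seed Seed for the participant noise.
#' @return Tibble in the schema read by [read_human_summary()].
#' @export
synthetic_human_summary <- function(n_participants = 12, seed = 42) {
  set.seed(seed)
  base <- tidyr::expand_grid(condition_grid(),
                             trial_type = c("target", "foil"))
  cell_mean <- function(speed_kmh, n_items, trial_type, metric) {
    hs <- as.numeric(speed_kmh == 120)
    hi <- as.numeric(n_items == 9)
    tg <- as.numeric(trial_type == "target")
    switch(metric,
      trial_time = 3.2 + 0.1 * hs - 0.9 * tg + 1.1 * hi,
      offset_sd = 0.08 + 0.06 * hs - 0.03 * tg + 0.03 * hi,
      n_lane_deviations = 0.03 + 0.05 * hs - 0.01 * tg - 0.01 * hi,
      n_incar_glances = 1.8 + 0.1 * hs - 0.5 * tg + 0.5 * hi,
      mean_incar_glance_duration = 1.0 - 0.0 * hs - 0.2 * tg + 0.2 * hi)
  }
  grid <- tidyr::expand_grid(base, metric = metric_names(),
                             participant = seq_len(n_participants))
  grid$value <- purrr::pmap_dbl(
    grid[c("speed_kmh", "n_items", "trial_type", "metric")],
    function(speed_kmh, n_items, trial_type, metric) {
      m <- cell_mean(speed_kmh, n_items, trial_type, metric)
      max(0, m * (1 + rnorm(1, 0, 0.15)))
    })
  grid
}

#' Write a trial trace to disk
#'
#' Writes the event timeline as a flat CSV and, alongside it, the lateral
#' offset samples (`<stem>_offsets.csv`).
#'
#' @param trace A `trial_trace`.
#' @param path CSV path for the event table.
#' @return `path`, invisibly.
#' @export
write_trace <- function(trace, path) {
  utils::write.csv(trace$events, path, row.names = FALSE)
  off_path <- sub("\\.csv$", "_offsets.csv", path)
  utils::write.csv(trace$offsets, off_path, row.names = FALSE)
  invisible(path)
}
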