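# The 2x2 experiment: glance extraction, metrics, aggregation, fit indices
# and the directional reproduction suite.

# hand-built minimal trace for metric oracles
make_fake_trace <- function(offsets, events, trial_time,
                            target_present = FALSE) {
  structure(list(
    events = events,
    offsets = tibble::tibble(t = seq_along(offsets), offset_m = offsets),
    target_present = target_present,
    completed = TRUE,
    aborted = FALSE,
    trial_time = trial_time,
    speed_kmh = 60,
    n_items = 6L
  ), class = "trial_trace")
}

fake_events <- function() {
  tibble::tibble(
    t_start = c(0, 1.0, 1.273, 2.5, 2.773),
    t_end = c(1.0, 1.273, 2.5, 2.773, 4.0),
    kind = c("drive_cycle", "switch", "search_encode", "switch", "drive_cycle"),
    focus = c("drive", "drive", "search", "search", "drive"),
    to_focus = c(NA, "search", NA, "drive", NA),
    lateral_offset_m = 0, r_d = 0, r_s = 0, item = NA_integer_)
}

test_that("condition_grid is exactly the 2x2 crossing", {
  g <- condition_grid()
  expect_equal(nrow(g), 4)
  expect_setequal(g$speed_kmh, c(60, 120))
  expect_setequal(g$n_items, c(6L, 9L))
  expect_equal(nrow(dplyr::distinct(g)), 4)
})

test_that("extract_glances partitions the timeline into road and in-car spans", {
  trace <- make_fake_trace(rep(0, 4), fake_events(), trial_time = 4.0)
  gl <- extract_glances(trace)
  expect_identical(gl$type, c("road", "incar", "road"))
  # the in-car span runs from switch-out start to switch-back start
  expect_equal(gl$t_start, c(0, 1.0, 2.5))
  expect_equal(gl$t_end, c(1.0, 2.5, 4.0))
  expect_equal(sum(gl$duration), trace$trial_time)
})

test_that("compute_metrics matches hand-computed oracles", {
  off <- c(0, 2, 2.2, 0, 3, 1, -2.5)
  trace <- make_fake_trace(off, fake_events(), trial_time = 4.0)
  m <- compute_metrics(trace, lane_half_bound_m = 1.75)
  expect_equal(m$trial_time, 4.0)
  expect_equal(m$offset_sd, sd(off))
  # three excursions beyond 1.75 m, each counted once at onset
  expect_identical(m$n_lane_deviations, 3L)
  expect_identical(m$n_incar_glances, 1L)
  expect_equal(m$mean_incar_glance_duration, 1.5)
  expect_identical(m$trial_type, "foil")
})

test_that("aggregate_metrics averages within then across participants", {
  base <- tidyr::expand_grid(participant = 1:2, trial = 1:2)
  mk <- function(vals) {
    tibble::tibble(base,
                   speed_kmh = 60, n_items = 6L, trial_type = "foil",
                   trial_time = vals, offset_sd = vals,
                   n_lane_deviations = vals, n_incar_glances = vals,
                   mean_incar_glance_duration = vals)
  }
  # participant means 1 and 3 -> mean 2, SE 1 (closed form at n = 2)
  m <- mk(c(0.5, 1.5, 2.5, 3.5))
  agg <- aggregate_metrics(m)
  expect_true(all(agg$mean == 2))
  expect_true(all(agg$se == 1))
  expect_true(all(agg$n == 2))

  # single participant: aggregate equals the participant mean
  one <- mk(c(1, 5, NA, NA))[1:2, ]
  agg1 <- aggregate_metrics(one)
  expect_true(all(agg1$mean == 3))

  # invariant to row order
  shuffled <- m[c(3, 1, 4, 2), ]
  expect_equal(aggregate_metrics(shuffled), agg)
})

test_that("compute_fit_indices matches identity, shift and OLS oracles", {
  model <- tidyr::expand_grid(speed_kmh = c(60, 120), n_items = c(6L, 9L),
                              trial_type = c("target", "foil"),
                              metric = "trial_time")
  model$mean <- c(1, 2, 3, 4, 5, 6, 7, 8)
  human <- model
  human$sd <- 2

  # suppressWarnings: lm flags these exact-fit cases as essentially perfect
  fit <- suppressWarnings(compute_fit_indices(model, human))
  expect_equal(fit$absolute_error, 0)
  expect_equal(fit$r_squared, 1)

  # constant shift: absolute error c, R^2 still 1
  shifted <- human
  shifted$mean <- shifted$mean + 0.7
  fit2 <- suppressWarnings(compute_fit_indices(model, shifted))
  expect_equal(fit2$absolute_error, 0.7)
  expect_equal(fit2$error_in_sd_units, 0.7 / 2)
  expect_equal(fit2$r_squared, 1)

  # independent OLS oracle on four cells
  model4 <- model[model$trial_type == "foil", ]
  model4$mean <- c(1.1, 1.9, 3.2, 3.8)
  human4 <- human[human$trial_type == "foil", ]
  human4$mean <- c(1, 2, 3, 4)
  fit3 <- compute_fit_indices(model4, human4)
  oracle <- summary(lm(c(1, 2, 3, 4) ~ c(1.1, 1.9, 3.2, 3.8)))$r.squared
  expect_equal(fit3$r_squared, oracle)
  expect_equal(fit3$absolute_error, mean(abs(c(1.1, 1.9, 3.2, 3.8) - 1:4)))
  expect_equal(fit3$relative_error, fit3$absolute_error / mean(1:4))

  # missing cells abort
  expect_error(compute_fit_indices(model, human[human$speed_kmh == 60, ]),
               "cover")
})

test_that("bundled synthetic human summary reads with the expected schema", {
  h <- read_human_summary()
  expect_named(h, c("speed_kmh", "n_items", "trial_type", "metric",
                    "mean", "sd", "n"))
  expect_equal(nrow(h), 8 * 5)  # 4 conditions x 2 trial types x 5 metrics
  expect_true(all(h$n == 12))
  expect_true(all(h$mean >= 0))
  pooled <- read_human_summary(by_trial_type = FALSE)
  expect_equal(nrow(pooled), 4 * 5)
  # the generator is deterministic given its seed
  s1 <- synthetic_human_summary(n_participants = 3, seed = 5)
  s2 <- synthetic_human_summary(n_participants = 3, seed = 5)
  expect_identical(s1, s2)
})

test_that("run_condition produces the balanced per-trial metric table", {
  pol <- get_policies()
  m <- run_condition(pol, n_participants = 2, n_trials = 4, seed = 31)
  expect_equal(nrow(m), 8)
  expect_true(all(metric_names <- c("trial_time", "offset_sd",
                                    "n_lane_deviations", "n_incar_glances",
                                    "mean_incar_glance_duration") %in% names(m)))
  counts <- table(m$participant, m$trial_type)
  expect_true(all(counts == 2))
  expect_true(all(m$speed_kmh == 60))
  expect_true(all(m$n_items == 6L))
  expect_error(run_condition(pol, 1, 3, 1), "even")

  # end-to-end determinism given (policies, seed)
  m2 <- run_condition(pol, n_participants = 2, n_trials = 4, seed = 31)
  expect_identical(m, m2)
})

test_that("the scaled-down experiment runs within its time budget", {
  exp <- get_experiment()
  expect_equal(nrow(exp$metrics), 4 * 4 * 24)
  expect_length(exp$policies, 4)
  expect_lt(get_experiment_minutes(), 15)
  # all four condition cells present
  cells <- dplyr::distinct(exp$metrics, speed_kmh, n_items)
  expect_equal(nrow(cells), 4)
})

test_that("directional condition effects reproduce the human effect signs", {
  m <- get_experiment()$metrics
  i9 <- m[m$n_items == 9, ]
  i6 <- m[m$n_items == 6, ]
  # more items: longer trials, more and longer in-car glances
  ci <- boot_diff_ci(i9$trial_time, i6$trial_time)
  expect_gt(ci[1], 0)
  ci <- boot_diff_ci(i9$n_incar_glances, i6$n_incar_glances)
  expect_gt(ci[1], 0)
  ci <- boot_diff_ci(i9$mean_incar_glance_duration,
                     i6$mean_incar_glance_duration)
  expect_gt(ci[1], 0)
  # higher speed: larger lateral variability
  s120 <- m[m$speed_kmh == 120, ]
  s60 <- m[m$speed_kmh == 60, ]
  ci <- boot_diff_ci(s120$offset_sd, s60$offset_sd)
  expect_gt(ci[1], 0)
  # foil screens take longer than target-present ones
  ci <- boot_diff_ci(m$trial_time[m$trial_type == "foil"],
                     m$trial_time[m$trial_type == "target"])
  expect_gt(ci[1], 0)
})

test_that("autoplot and plot_training return ggplot objects", {
  pol <- get_policies()
  trace <- run_trial(pol, target_present = FALSE, seed = 41)
  expect_s3_class(ggplot2::autoplot(trace), "ggplot")
  summ <- aggregate_metrics(get_experiment()$metrics)
  expect_s3_class(ggplot2::autoplot(summ), "ggplot")
  expect_s3_class(plot_training(pol$drive_log), "ggplot")
})

test_that("traces serialize to CSV alongside their offset samples", {
  pol <- get_policies()
  trace <- run_trial(pol, target_present = TRUE, seed = 42)
  path <- tempfile(fileext = ".csv")
  on.exit(unlink(c(path, sub("\\.csv$", "_offsets.csv", path))))
  write_trace(trace, path)
  ev <- utils::read.csv(path)
  expect_equal(nrow(ev), nrow(trace$events))
  off <- utils::read.csv(sub("\\.csv$", "_offsets.csv", path))
  expect_equal(nrow(off), nrow(trace$offsets))
})
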