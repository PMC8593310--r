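#' Supervisory attention allocation between driving and search
#'
#' The top-level policy observes the best-available-action utilities of the
#' two trained subtask policies (max q_d and max q_s, each discretized) plus
#' the task currently holding attention, and chooses between two actions,
#' `drive` and `search`. Changing focus costs switch-cost downtime during
#' which neither task progresses and driving runs blind; while searching,
#' driving is simulated forward without observations for the duration of
#' each eye-movement action (the driver can still steer on the propagated
#' belief). The supervisory reward is the joint subtask reward
#' `w * R_d + R_s` accrued over the step.
#'
#' @name supervisory
NULL

FOCUS_DRIVE <- 1L
FOCUS_SEARCH <- 2L

n_supervisory_states <- function(q_bins) q_bins * q_bins * 2L

# discretize a max-Q value into 1..q_bins over a calibrated range
q_to_bin <- function(q, range, q_bins) {
  w <- (range[2] - range[1]) / q_bins
  if (w <= 0) return(1L)
  as.integer(clip(floor((q - range[1]) / w) + 1, 1L, q_bins))
}

supervisory_state_index <- function(qd_bin, qs_bin, focus, q_bins) {
  qd_bin + (qs_bin - 1L) * q_bins + (focus - 1L) * q_bins * q_bins
}

# --- joint trial state ------------------------------------------------------

# fresh joint state: car at lane centre (position known), fresh layout,
# attention initially on the road
new_joint_state <- function(policies, target_present) {
  cfg <- policies$config
  dp <- cfg$driving
  js <- new.env(parent = emptyenv())
  js$ds <- driving_state(0, 0, dp)
  js$db <- point_belief(offset_to_bin(0, dp), dp)
  se <- new.env(parent = emptyenv())
  se$state <- generate_layout(cfg$search, target_present = target_present)
  se$belief <- empty_search_belief(se$state)
  se$cells <- layout_cells(se$state, cfg$search)
  se$params <- cfg$search
  js$se <- se
  js$focus <- FOCUS_DRIVE
  js$t <- 0
  js
}

driving_policy_index <- function(js, dp) {
  s <- belief_summary(js$db)
  driving_state_index(s$map_position, entropy_to_bin(s$entropy, dp),
                      steering_to_index(js$ds$steering, dp), dp)
}

search_policy_index <- function(js) {
  se <- js$se
  search_state_index(cell_of(se$belief$fixation, se$params),
                     cell_pattern(se$cells, se$belief$encoded))
}

# raw supervisory observation (continuous max-Q values + focus)
supervisory_observe <- function(js, policies) {
  list(qd = max_q(policies$drive_q, driving_policy_index(js, policies$config$driving)),
       qs = max_q(policies$search_q, search_policy_index(js)),
       focus = js$focus)
}

supervisory_obs_index <- function(obs, policies) {
  cfg <- policies$config
  if (is.null(policies$calib)) return(1L)  # pre-calibration warm-up
  supervisory_state_index(
    q_to_bin(obs$qd, policies$calib$qd_range, cfg$q_bins),
    q_to_bin(obs$qs, policies$calib$qs_range, cfg$q_bins),
    obs$focus, cfg$q_bins)
}

# simulate driving blind for `duration` seconds in dt_drive sub-steps:
# the driving policy keeps steering on its propagated belief, no
# observations arrive, lane penalties accrue; returns accrued R_d
blind_drive <- function(js, duration, policies, acc = NULL) {
  dp <- policies$config$driving
  dt <- dp$dt_drive_s
  r_d <- 0
  remaining <- duration
  while (remaining > 1e-9) {
    chunk <- min(dt, remaining)
    a <- select_action(policies$drive_q, driving_policy_index(js, dp),
                       policies$eval_tau)
    js$ds <- simulate_step(js$ds, dp$action_set[a], dp, duration = chunk)
    js$db <- belief_predict(js$db, a, policies$tau_d)
    r_d <- r_d + driving_reward(js$ds, dp, duration = chunk)
    js$t <- js$t + chunk
    remaining <- remaining - chunk
    if (!is.null(acc)) push_offset(acc, js$t, js$ds$lateral_offset_m)
  }
  r_d
}

# --- trace accumulator ------------------------------------------------------

new_trace_acc <- function() {
  acc <- new.env(parent = emptyenv())
  acc$ev <- list()
  acc$off_t <- numeric(0)
  acc$off_x <- numeric(0)
  acc
}

push_event <- function(acc, t_start, t_end, kind, focus, to_focus,
                       offset, r_d, r_s, item = NA_integer_) {
  acc$ev[[length(acc$ev) + 1L]] <-
    list(t_start = t_start, t_end = t_end, kind = kind, focus = focus,
         to_focus = to_focus, lateral_offset_m = offset, r_d = r_d, r_s = r_s,
         item = item)
}

push_offset <- function(acc, t, offset) {
  n <- length(acc$off_t) + 1L
  acc$off_t[n] <- t
  acc$off_x[n] <- offset
}

acc_to_trace <- function(acc, js, policies, target_present, completed, aborted) {
  ev <- acc$ev
  events <- tibble::tibble(
    t_start = vapply(ev, `[[`, numeric(1), "t_start"),
    t_end = vapply(ev, `[[`, numeric(1), "t_end"),
    kind = vapply(ev, `[[`, character(1), "kind"),
    focus = vapply(ev, `[[`, character(1), "focus"),
    to_focus = vapply(ev, `[[`, character(1), "to_focus"),
    lateral_offset_m = vapply(ev, `[[`, numeric(1), "lateral_offset_m"),
    r_d = vapply(ev, `[[`, numeric(1), "r_d"),
    r_s = vapply(ev, `[[`, numeric(1), "r_s"),
    item = vapply(ev, `[[`, integer(1), "item")
  )
  structure(list(
    events = events,
    offsets = tibble::tibble(t = acc$off_t, offset_m = acc$off_x),
    target_present = target_present,
    completed = completed,
    aborted = aborted,
    trial_time = js$t,
    speed_kmh = policies$config$speed_kmh,
    n_items = policies$config$n_items
  ), class = "trial_trace")
}

#' @export
print.trial_trace <- function(x, ...) {
  cat(sprintf(
    "<trial_trace> %s, %d items @ %g km/h: %.2f s, %d events%s\n",
    if (x$target_present) "target" else "foil", x$n_items, x$speed_kmh,
    x$trial_time, nrow(x$events), if (x$aborted) " [aborted]" else ""))
  invisible(x)
}

#' @export
as_tibble.trial_trace <- function(x, ...) x$events

focus_label <- function(f) if (f == FOCUS_DRIVE) "drive" else "search"

#' One supervisory step
#'
#' Applies one supervisory action to a joint trial state. If the action
#' differs from the task currently in focus, a switch event of
#' `switch_cost_s` is emitted first, with driving simulated blind
#' throughout. A `drive` action then runs one attended driving cycle
#' (steer, predict, observe, correct); a `search` action runs one
#' policy-chosen encode with driving simulated blind for the eye-movement
#' duration.
#'
#' @param action `FOCUS_DRIVE` (1) or `FOCUS_SEARCH` (2).
#' @param js Joint state environment from `new_joint_state()` (internal;
#'   exposed for inspection and testing through [run_trial()]).
#' @param policies A trained [train_policies()] object.
#' @param acc Optional trace accumulator.
#' @return List with the joint supervisory `reward`, its `r_d`/`r_s`
#'   components, and `done`.
#' @keywords internal
supervisory_step <- function(action, js, policies, acc = NULL) {
  cfg <- policies$config
  dp <- cfg$driving
  w <- cfg$reward_weight_drive
  r_total <- 0
  r_d_all <- 0
  r_s_all <- 0
  done <- FALSE

  if (action != js$focus) {
    t0 <- js$t
    r_d <- blind_drive(js, cfg$switch_cost_s, policies, acc)
    if (!is.null(acc)) {
      push_event(acc, t0, js$t, "switch", focus_label(js$focus),
                 focus_label(action), js$ds$lateral_offset_m, r_d, 0)
    }
    js$focus <- action
    r_total <- r_total + w * r_d
    r_d_all <- r_d_all + r_d
  }

  if (action == FOCUS_DRIVE) {
    t0 <- js$t
    a <- select_action(policies$drive_q, driving_policy_index(js, dp),
                       policies$eval_tau)
    js$ds <- simulate_step(js$ds, dp$action_set[a], dp)
    js$db <- belief_predict(js$db, a, policies$tau_d)
    obs <- sample_observation(offset_to_bin(js$ds$lateral_offset_m, dp), dp)
    js$db <- belief_correct(js$db, obs, dp)
    r_d <- driving_reward(js$ds, dp)
    js$t <- js$t + dp$dt_drive_s
    if (!is.null(acc)) {
      push_offset(acc, js$t, js$ds$lateral_offset_m)
      push_event(acc, t0, js$t, "drive_cycle", "drive", NA_character_,
                 js$ds$lateral_offset_m, r_d, 0)
    }
    r_total <- r_total + w * r_d
    r_d_all <- r_d_all + r_d
  } else {
    t0 <- js$t
    sa <- select_action(policies$search_q, search_policy_index(js),
                        policies$eval_tau)
    res <- search_env_act(js$se, sa)
    r_d <- blind_drive(js, res$elapsed, policies, acc)
    if (!is.null(acc)) {
      push_event(acc, t0, js$t, "search_encode", "search", NA_character_,
                 js$ds$lateral_offset_m, r_d, res$reward,
                 item = if (is.na(res$item)) NA_integer_ else res$item)
    }
    done <- res$done
    r_total <- r_total + w * r_d + res$reward
    r_d_all <- r_d_all + r_d
    r_s_all <- r_s_all + res$reward
  }
  list(reward = r_total, r_d = r_d_all, r_s = r_s_all, done = done)
}

# shared trial loop: runs one full trial under a supervisory action source,
# optionally performing SARSA updates against a mutable Q environment
# (`sup_train`, holding $q and $visits) and optionally collecting a trace /
# raw q observations
run_trial_engine <- function(policies, target_present,
                             sup_policy = "learned",
                             sup_train = NULL, lp = NULL, tau_sm = NULL,
                             trace = TRUE, collect_q = FALSE,
                             gamma = NULL) {
  cfg <- policies$config
  js <- new_joint_state(policies, target_present)
  acc <- if (trace) new_trace_acc() else NULL
  if (trace) push_offset(acc, 0, 0)
  q_log <- if (collect_q) list(qd = numeric(0), qs = numeric(0)) else NULL
  if (is.null(tau_sm)) tau_sm <- policies$eval_tau
  train <- !is.null(sup_train)
  qmat <- if (train) NULL else if (sup_policy == "learned") policies$sup_q$q

  sup_q_row <- function(s_idx) {
    if (train) sup_train$q[s_idx, ] else qmat[s_idx, ]
  }
  choose <- function(s_idx, step_i) {
    switch(sup_policy,
      learned = sample.int(2L, 1, prob = softmax_probs(sup_q_row(s_idx), tau_sm)),
      always_drive = FOCUS_DRIVE,
      alternate = if (step_i %% 2 == 1) FOCUS_DRIVE else FOCUS_SEARCH,
      random = sample.int(2L, 1),
      abort("unknown supervisory policy"))
  }

  if (is.null(gamma)) gamma <- if (is.null(lp)) 0.95 else lp$gamma
  obs <- supervisory_observe(js, policies)
  s <- supervisory_obs_index(obs, policies)
  step_i <- 1L
  a <- choose(s, step_i)
  total_reward <- 0
  discounted_return <- 0
  disc <- 1
  completed <- FALSE
  aborted <- FALSE
  repeat {
    if (collect_q) {
      q_log$qd <- c(q_log$qd, obs$qd)
      q_log$qs <- c(q_log$qs, obs$qs)
    }
    out <- supervisory_step(a, js, policies, acc)
    total_reward <- total_reward + out$reward
    discounted_return <- discounted_return + disc * out$reward
    disc <- disc * gamma
    if (out$done) completed <- TRUE
    if (js$t >= cfg$max_trial_s && !out$done) aborted <- TRUE
    terminal <- completed || aborted
    if (terminal) {
      if (train) {
        al <- lp$alpha / (1 + lp$alpha_decay * sup_train$nsa[s, a])
        sup_train$nsa[s, a] <- sup_train$nsa[s, a] + 1L
        sup_train$q[s, a] <- sarsa_update(
          sup_train$q[s, a], out$reward, 0, al, lp$gamma)
        sup_train$visits[s] <- sup_train$visits[s] + 1L
      }
      break
    }
    obs <- supervisory_observe(js, policies)
    s2 <- supervisory_obs_index(obs, policies)
    step_i <- step_i + 1L
    a2 <- choose(s2, step_i)
    if (train) {
      al <- lp$alpha / (1 + lp$alpha_decay * sup_train$nsa[s, a])
      sup_train$nsa[s, a] <- sup_train$nsa[s, a] + 1L
      sup_train$q[s, a] <- sarsa_update(
        sup_train$q[s, a], out$reward,
        sup_train$q[s2, a2], al, lp$gamma)
      sup_train$visits[s] <- sup_train$visits[s] + 1L
    }
    s <- s2; a <- a2
  }
  list(trace = if (trace) acc_to_trace(acc, js, policies, target_present,
                                       completed, aborted) else NULL,
       reward = total_reward, discounted_return = discounted_return,
       completed = completed, aborted = aborted,
       trial_time = js$t, q_log = q_log)
}

#' Evaluate a supervisory allocation policy over seeded trials
#'
#' Runs dual-task trials (alternating target-present / foil screens) under
#' the learned supervisory policy or a fixed baseline and reports per-trial
#' outcomes. `discounted_return` is the per-decision-step discounted sum of
#' joint rewards — the objective the supervisory learner optimizes. The
#' undiscounted `reward` cannot separate allocation policies that complete
#' the search with similar encoding effort, because waiting costs nothing
#' in raw reward terms; the discounted return penalizes the later
#' completion that over-frequent switching causes.
#'
#' @param policies A trained [train_policies()] object.
#' @param n_trials Number of trials.
#' @param sup_policy `"learned"`, `"always_drive"`, `"alternate"` or
#'   `"random"`.
#' @param gamma Discount per supervisory decision step.
#' @param seed Optional seed.
#' @return A tibble with one row per trial: `trial`, `target_present`,
#'   `reward`, `discounted_return`, `trial_time`, `completed`, `aborted`.
#' @export
evaluate_supervisory_policy <- function(policies, n_trials = 100,
                                        sup_policy = "learned",
                                        gamma = 0.95, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  purrr::map_dfr(seq_len(n_trials), function(i) {
    tp <- i %% 2 == 0
    out <- run_trial_engine(policies, target_present = tp,
                            sup_policy = sup_policy, trace = FALSE,
                            gamma = gamma)
    tibble::tibble(trial = i, target_present = tp, reward = out$reward,
                   discounted_return = out$discounted_return,
                   trial_time = out$trial_time, completed = out$completed,
                   aborted = out$aborted)
  })
}

#' Simulate one dual-task trial
#'
#' Starts the car at the lane centre with a known position, lays out a
#' fresh search screen, and iterates supervisory steps until the search
#' trial completes (target found, or all items encoded on a foil screen).
#' Trials that run past the safety valve (`max_trial_s`) are aborted and
#' flagged.
#'
#' @param policies A trained [train_policies()] object.
#' @param target_present Whether the screen contains the target.
#' @param seed Optional seed for reproducibility.
#' @param sup_policy `"learned"` (default) or a fixed baseline:
#'   `"always_drive"`, `"alternate"`, `"random"`.
#' @return A `trial_trace` object: `$events` (contiguous timeline of
#'   drive_cycle / search_encode / switch spans), `$offsets` (lateral
#'   offset sampled at every driving sub-step), completion flags and trial
#'   time.
#' @export
run_trial <- function(policies, target_present = TRUE, seed = NULL,
                      sup_policy = "learned") {
  if (!is.null(seed)) set.seed(seed)
  run_trial_engine(policies, target_present, sup_policy = sup_policy,
                   trace = TRUE)$trace
}

# warm-up calibration of the supervisory observation bins: run trials with
# uniform-random attention allocation and record the raw max-Q ranges
calibrate_q_bins <- function(policies, n_trials = 20) {
  qd <- numeric(0); qs <- numeric(0)
  for (i in seq_len(n_trials)) {
    out <- run_trial_engine(policies, target_present = i %% 2 == 0,
                            sup_policy = "random", trace = FALSE,
                            collect_q = TRUE)
    qd <- c(qd, out$q_log$qd)
    qs <- c(qs, out$q_log$qs)
  }
  pad <- function(r) if (diff(r) <= 0) r + c(-0.5, 0.5) else r
  list(qd_range = pad(range(qd)), qs_range = pad(range(qs)))
}

#' Train the supervisory attention-allocation policy
#'
#' Requires the two subtask policies (enforced ordering): SARSA runs over
#' episodes that are complete dual-task trials, with the discretized
#' (max q_d, max q_s, focus) observation as the state and \{drive, search\}
#' as the actions.
#'
#' @param policies A partially trained policies object holding `tau_d`,
#'   `drive_q`, `search_q` and `calib`.
#' @param lp A [learning_params()] object for the supervisory learner.
#' @param p_target Probability a training screen is target-present.
#' @return The policies object with `sup_q` trained and `sup_log` attached.
#' @export
train_supervisory <- function(policies, lp, p_target = 0.5) {
  if (is.null(policies$drive_q) || is.null(policies$search_q)) {
    abort("subtask policies must be trained before the supervisory policy")
  }
  if (is.null(policies$calib)) {
    abort("supervisory observation bins must be calibrated first")
  }
  n_ep <- lp$n_episodes
  n_sup <- n_supervisory_states(policies$config$q_bins)
  sup_train <- new.env(parent = emptyenv())
  sup_train$q <- matrix(0, n_sup, 2L)
  sup_train$visits <- integer(n_sup)
  sup_train$nsa <- matrix(0L, n_sup, 2L)
  ret <- numeric(n_ep)
  tt <- numeric(n_ep)
  for (ep in seq_len(n_ep)) {
    tau <- anneal_temperature(ep, lp)
    out <- run_trial_engine(policies, target_present = runif(1) < p_target,
                            sup_train = sup_train, lp = lp, tau_sm = tau,
                            trace = FALSE)
    ret[ep] <- out$reward
    tt[ep] <- out$trial_time
    if (!all(is.finite(sup_train$q))) {
      abort(sprintf("supervisory Q-table diverged at episode %d", ep))
    }
  }
  policies$sup_q <- new_qtable(n_sup, 2L)
  policies$sup_q$q <- sup_train$q
  policies$sup_q$visits <- sup_train$visits
  policies$sup_log <- tibble::tibble(episode = seq_len(n_ep), return = ret,
                                     trial_time = tt)
  policies
}

#' Train all three policies for one condition
#'
#' The full training pipeline for a speed-by-set-size condition, in the
#' enforced order: (1) learn the driving transition model from random-action
#' rollouts, (2) train the driving policy, (3) train the search policy,
#' (4) calibrate the supervisory observation bins in a random-allocation
#' warm-up, (5) train the supervisory policy on complete dual-task trials.
#'
#' @param speed_kmh,n_items Condition values (ignored if `config` given).
#' @param profile Training-effort profile, see [training_profile()].
#' @param seed Master seed; the run is reproducible given (seed, config).
#' @param config Optional [multitask_config()] overriding the condition
#'   defaults.
#' @param lp_driving,lp_search,lp_supervisory Optional [learning_params()]
#'   overrides; episode counts default to the profile.
#' @param drive_observe Observation regime for driving training; see
#'   [make_driving_env()].
#' @return A `multitask_policies` object bundling the config, transition
#'   model, the three Q-tables, calibration ranges and training logs.
#' @export
train_policies <- function(speed_kmh = 60, n_items = 6,
                           profile = c("fast", "full"),
                           seed = 1, config = NULL,
                           lp_driving = NULL, lp_search = NULL,
                           lp_supervisory = NULL,
                           drive_observe = "intermittent") {
  prof <- training_profile(match.arg(profile))
  if (is.null(config)) config <- multitask_config(speed_kmh, n_items)
  if (is.null(lp_driving)) lp_driving <- learning_params(n_episodes = prof$driving)
  if (is.null(lp_search)) {
    # the exploration temperature must scale with the task's utility range:
    # search values approach reward_found, so a start temperature of
    # reward_found / 2 keeps early selection genuinely exploratory (a
    # start of 1 is effectively greedy once utilities reach ~3, locking
    # the policy onto early revisit cycles before alternatives are tried)
    lp_search <- learning_params(n_episodes = prof$search,
                                 tau_start = config$search$reward_found / 2)
  }
  if (is.null(lp_supervisory)) {
    # same utility-range argument as for search: supervisory returns are
    # dominated by the search completion reward, so the exploration
    # temperature starts at reward_found / 2 as well
    lp_supervisory <- learning_params(
      n_episodes = prof$supervisory,
      tau_start = config$search$reward_found / 2)
  }
  set.seed(seed)

  tau_d <- learn_transition_model(config$driving, prof$rollout_steps)
  denv <- make_driving_env(config$driving, tau_d, observe = drive_observe)
  dres <- train_policy(denv, lp_driving)
  senv <- make_search_env(config$search)
  sres <- train_policy(senv, lp_search)

  policies <- structure(list(
    config = config,
    tau_d = tau_d,
    drive_q = dres$qtable,
    search_q = sres$qtable,
    sup_q = NULL,
    calib = NULL,
    eval_tau = lp_supervisory$eval_tau,
    drive_log = dres$log,
    search_log = sres$log,
    sup_log = NULL,
    seed = seed
  ), class = "multitask_policies")
  policies$calib <- calibrate_q_bins(policies, prof$calibration_trials)
  train_supervisory(policies, lp_supervisory)
}

#' @export
print.multitask_policies <- function(x, ...) {
  cat(sprintf("<multitask_policies> %g km/h, %d items\n",
              x$config$speed_kmh, x$config$n_items))
  cat(sprintf("  driving Q: %d/%d states visited\n",
              sum(x$drive_q$visits > 0), x$drive_q$n_states))
  cat(sprintf("  search  Q: %d/%d states visited\n",
              sum(x$search_q$visits > 0), x$search_q$n_states))
  if (!is.null(x$sup_q)) {
    cat(sprintf("  supervisory Q: %d/%d states visited\n",
                sum(x$sup_q$visits > 0), x$sup_q$n_states))
  }
  invisible(x)
}

#' @rdname tidy.qtable
#' @export
tidy.multitask_policies <- function(x, ...) {
  dplyr::bind_rows(
    dplyr::mutate(tidy(x$drive_q), policy = "driving"),
    dplyr::mutate(tidy(x$search_q), policy = "search"),
    if (!is.null(x$sup_q)) dplyr::mutate(tidy(x$sup_q), policy = "supervisory")
  )
}

#' @rdname glance.qtable
#' @export
glance.multitask_policies <- function(x, ...) {
  dplyr::bind_rows(
    dplyr::mutate(glance(x$drive_q), policy = "driving"),
    dplyr::mutate(glance(x$search_q), policy = "search"),
    if (!is.null(x$sup_q)) {
      dplyr::mutate(glance(x$sup_q), policy = "supervisory")
    }
  )
}
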