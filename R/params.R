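#' Driving-task parameters
#'
#' Configuration of the lane-keeping POMDP: a car at fixed speed on a
#' slightly left-bending highway lane, steered by discrete adjustments to a
#' bounded steering state, with Gaussian lateral action noise and a noisy
#' discretized observation of lateral position.
#'
#' The lateral dynamics are the minimal speed-sensitive linear form
#' `offset' = offset + v * dt * steering' + drift * dt + N(0, sigma_d)`,
#' so that the speed manipulation (60 vs 120 km/h) has mechanical effect:
#' the same steering state moves the car laterally twice as fast at twice
#' the speed.
#'
#' @param speed_kmh Fixed vehicle speed in km/h (condition value, 60 or 120).
#' @param lane_width_m Lane width in metres; the lane-deviation bound is
#'   half of it (the car is treated as a point).
#' @param n_position_bins Odd number of discretization bins for the lateral
#'   offset over `[-offset_range_m, offset_range_m]`; odd so a centre bin
#'   exists.
#' @param offset_range_m Half-range of the discretized lateral offset, in
#'   metres. Offsets beyond it clamp to the edge bins.
#' @param sigma_d Standard deviation of per-cycle Gaussian lateral action
#'   noise, metres. Hand-set to give reliable but nondeterministic driving.
#' @param p_obs_correct Probability that a lane-position observation reports
#'   the true discretized bin; the remainder is spread uniformly over the
#'   other bins.
#' @param dt_drive_s Duration of one driving cycle, seconds.
#' @param curvature_drift_mps Constant lateral drift in m/s emulating the
#'   road's slight leftward bend; 0 disables it.
#' @param penalty_rate Negative reward per second spent beyond the lane
#'   bound (reward is 0 inside the closed interval).
#' @param steering_max Steering state is clipped to
#'   `[-steering_max, steering_max]` (dimensionless).
#' @param steering_step Granularity of the steering grid; all steering
#'   deltas in `action_set` must be multiples of it.
#' @param action_set Ordered steering adjustments available per cycle; must
#'   contain 0 (a no-op).
#' @param n_entropy_bins Number of equal-width bins used to discretize
#'   belief entropy (in nats, over `[0, log(n_position_bins)]`) when forming
#'   the tabular policy state.
#'
#' @return A `driving_params` list with derived fields `lane_half_bound_m`,
#'   `bin_width_m`, `bin_centers`, `steering_values` and `speed_mps`.
#' @examples
#' p <- driving_params(speed_kmh = 60)
#' p$lane_half_bound_m
#' @export
driving_params <- function(speed_kmh = 60,
                           lane_width_m = 3.5,
                           n_position_bins = 21,
                           offset_range_m = 3.5,
                           sigma_d = 0.05,
                           p_obs_correct = 0.9,
                           dt_drive_s = 0.25,
                           curvature_drift_mps = 0.02,
                           penalty_rate = 1,
                           steering_max = 0.1,
                           steering_step = 0.01,
                           action_set = c(-0.02, -0.01, 0, 0.01, 0.02),
                           n_entropy_bins = 5) {
  check_number(speed_kmh, "speed_kmh", lo = 0, strict_lo = TRUE)
  check_number(lane_width_m, "lane_width_m", lo = 0, strict_lo = TRUE)
  check_number(dt_drive_s, "dt_drive_s", lo = 0, strict_lo = TRUE)
  check_number(sigma_d, "sigma_d", lo = 0)
  check_number(p_obs_correct, "p_obs_correct", lo = 0, hi = 1, strict_lo = TRUE)
  if (n_position_bins %% 2 != 1 || n_position_bins < 3) {
    abort("`n_position_bins` must be odd (a centre bin must exist) and >= 3.")
  }
  if (!any(action_set == 0)) {
    abort("`action_set` must contain 0 (a no-op steering adjustment).")
  }
  bin_width <- 2 * offset_range_m / n_position_bins
  steering_values <- seq(-steering_max, steering_max, by = steering_step)
  structure(list(
    speed_kmh = speed_kmh,
    speed_mps = kmh_to_mps(speed_kmh),
    lane_width_m = lane_width_m,
    lane_half_bound_m = lane_width_m / 2,
    n_position_bins = as.integer(n_position_bins),
    offset_range_m = offset_range_m,
    bin_width_m = bin_width,
    bin_centers = seq(-offset_range_m + bin_width / 2, offset_range_m - bin_width / 2,
                      length.out = n_position_bins),
    sigma_d = sigma_d,
    p_obs_correct = p_obs_correct,
    dt_drive_s = dt_drive_s,
    curvature_drift_mps = curvature_drift_mps,
    penalty_rate = penalty_rate,
    steering_max = steering_max,
    steering_step = steering_step,
    steering_values = steering_values,
    action_set = action_set,
    n_entropy_bins = as.integer(n_entropy_bins)
  ), class = "driving_params")
}

#' Visual-search task parameters
#'
#' Configuration of the in-car visual-search POMDP: `n_items` items are
#' placed uniformly at random on a small display (degrees of visual angle),
#' at least `min_separation_deg` apart so each requires its own fixation.
#' Encoding and saccade timing follow the EMMA eye-movement model:
#' encoding time `T_e = K * (-log f) * exp(k * eccentricity)` and saccade
#' duration `T_s = t_prep + t_exec + D * t_sacc`.
#'
#' @param n_items Number of items per screen (condition value, 6 or 9).
#' @param extent_x_deg,extent_y_deg Display extent in degrees of visual
#'   angle; items are placed in
#'   `[-extent_x/2, extent_x/2] x [-extent_y/2, extent_y/2]`.
#' @param min_separation_deg Minimum pairwise item separation, degrees.
#' @param f Object frequency in `(0, 1]`; low for novel trigram stimuli.
#' @param K Encoding time constant, seconds.
#' @param k Eccentricity constant, per degree.
#' @param t_prep Saccade preparation time, seconds.
#' @param t_exec Saccade execution (non-distance) time, seconds.
#' @param t_sacc Saccade travel time per degree, seconds.
#' @param reward_found Positive reward on locating the target.
#' @param reward_foil_done Positive reward on exhausting a target-absent
#'   screen; defaults to `reward_found`, set 0 to reward only detection.
#' @param max_episode_steps Safety cap on encode actions per trial.
#'
#' @return A `search_params` list with the derived entry fixation point
#'   (`entry_fixation`, top-centre of the display).
#' @examples
#' search_params(n_items = 9)$min_separation_deg
#' @export
search_params <- function(n_items = 6,
                          extent_x_deg = 10,
                          extent_y_deg = 6,
                          min_separation_deg = 2,
                          f = 0.01,
                          K = 0.006,
                          k = 0.4,
                          t_prep = 0.135,
                          t_exec = 0.070,
                          t_sacc = 0.002,
                          reward_found = 10,
                          reward_foil_done = reward_found,
                          max_episode_steps = 60) {
  if (n_items < 1) abort("`n_items` must be >= 1.")
  check_number(f, "f", lo = 0, hi = 1, strict_lo = TRUE)
  check_number(min_separation_deg, "min_separation_deg", lo = 0, strict_lo = TRUE)
  for (nm in c("K", "k", "t_prep", "t_exec", "t_sacc")) {
    check_number(get(nm), nm, lo = 0, strict_lo = TRUE)
  }
  structure(list(
    n_items = as.integer(n_items),
    extent_x_deg = extent_x_deg,
    extent_y_deg = extent_y_deg,
    min_separation_deg = min_separation_deg,
    f = f, K = K, k = k,
    t_prep = t_prep, t_exec = t_exec, t_sacc = t_sacc,
    reward_found = reward_found,
    reward_foil_done = reward_foil_done,
    max_episode_steps = as.integer(max_episode_steps),
    entry_fixation = c(0, extent_y_deg / 2)
  ), class = "search_params")
}

#' SARSA learning hyperparameters
#'
#' @param alpha Initial learning rate in `(0, 1]`.
#' @param alpha_decay Per-(state, action) Robbins-Monro decay: the
#'   effective rate after `n` updates of a cell is
#'   `alpha / (1 + alpha_decay * n)`, so estimates settle as a cell is
#'   revisited; 0 keeps `alpha` constant.
#' @param gamma Discount factor in `[0, 1]`.
#' @param tau_start,tau_end Softmax exploration temperature, annealed
#'   linearly from `tau_start` to `tau_end` over the first `anneal_frac` of
#'   the episodes and held at `tau_end` thereafter, so late episodes refine
#'   the near-greedy policy. Both must be positive. Written `tau_sm`
#'   elsewhere to keep it distinct from the learned driving transition
#'   model `tau_d`.
#' @param anneal_frac Fraction of episodes over which the temperature
#'   anneals.
#' @param eval_tau Temperature used when simulating with a trained policy;
#'   small but positive, preserving mild stochasticity rather than acting
#'   greedily.
#' @param n_episodes Number of training episodes.
#'
#' @return A `learning_params` list.
#' @export
learning_params <- function(alpha = 0.1, alpha_decay = 0.02, gamma = 0.95,
                            tau_start = 1.0, tau_end = 0.05,
                            anneal_frac = 0.6,
                            eval_tau = 0.05, n_episodes = 1000) {
  check_number(alpha, "alpha", lo = 0, hi = 1, strict_lo = TRUE)
  check_number(alpha_decay, "alpha_decay", lo = 0)
  check_number(gamma, "gamma", lo = 0, hi = 1)
  check_number(tau_start, "tau_start", lo = 0, strict_lo = TRUE)
  check_number(tau_end, "tau_end", lo = 0, strict_lo = TRUE)
  check_number(eval_tau, "eval_tau", lo = 0, strict_lo = TRUE)
  if (n_episodes < 0) abort("`n_episodes` must be >= 0.")
  check_number(anneal_frac, "anneal_frac", lo = 0, hi = 1, strict_lo = TRUE)
  structure(list(alpha = alpha, alpha_decay = alpha_decay, gamma = gamma,
                 tau_start = tau_start, tau_end = tau_end,
                 anneal_frac = anneal_frac,
                 eval_tau = eval_tau, n_episodes = as.integer(n_episodes)),
            class = "learning_params")
}

#' Full dual-task configuration for one experimental condition
#'
#' Bundles the driving and search parameters with the supervisory settings:
#' the task-switch cost (by default the saccade duration for the measured
#' 34-degree road-to-display separation), the number of bins used to
#' discretize the two observed max-Q values, and the relative weight on the
#' driving reward in the joint supervisory reward `w * R_d + R_s`.
#'
#' @param speed_kmh Speed condition, km/h.
#' @param n_items Search set-size condition.
#' @param switch_cost_s Attention-switch downtime in seconds; `NULL` derives
#'   it as `saccade_time(display_separation_deg)`.
#' @param display_separation_deg Visual angle between the road vanishing
#'   point and the in-car display.
#' @param q_bins Bins per axis for discretizing the supervisory (max q_d,
#'   max q_s) observation; >= 2.
#' @param reward_weight_drive Weight `w` on `R_d` in the joint reward.
#' @param driving,search Parameter objects; defaults built from the
#'   condition values.
#' @param max_trial_s Safety valve: simulated trials abort (flagged) past
#'   this time.
#'
#' @return A `multitask_config` list.
#' @examples
#' cfg <- multitask_config(speed_kmh = 120, n_items = 9)
#' cfg$switch_cost_s  # 0.135 + 0.070 + 34 * 0.002
#' @export
multitask_config <- function(speed_kmh = 60, n_items = 6,
                             switch_cost_s = NULL,
                             display_separation_deg = 34,
                             q_bins = 12,
                             reward_weight_drive = 1,
                             driving = driving_params(speed_kmh = speed_kmh),
                             search = search_params(n_items = n_items),
                             max_trial_s = 60) {
  if (q_bins < 2) abort("`q_bins` must be >= 2.")
  if (is.null(switch_cost_s)) {
    switch_cost_s <- saccade_time(display_separation_deg, search)
  }
  check_number(switch_cost_s, "switch_cost_s", lo = 0)
  structure(list(
    speed_kmh = speed_kmh,
    n_items = as.integer(n_items),
    switch_cost_s = switch_cost_s,
    display_separation_deg = display_separation_deg,
    q_bins = as.integer(q_bins),
    reward_weight_drive = reward_weight_drive,
    driving = driving,
    search = search,
    max_trial_s = max_trial_s
  ), class = "multitask_config")
}

#' Training-effort profiles
#'
#' Episode budgets for the three learners and the transition-model rollout.
#' `"full"` is the study-scale budget; `"fast"` is a reduced budget for
#' quick runs and continuous testing. The fast driving budget is kept
#' comparatively high because lane keeping has the largest tabular state
#' space and its reward is sparse; with much fewer episodes the attended
#' driver is not yet reliable, which distorts everything built on top.
#' The search budgets are sized so the trained policy has near-zero
#' revisits on foil trials even at nine items, where each random layout
#' maps to a different cleared-cell pattern and state coverage is thin.
#'
#' @param profile `"full"` or `"fast"`.
#' @return Named list of episode/rollout counts.
#' @export
training_profile <- function(profile = c("fast", "full")) {
  profile <- match.arg(profile)
  if (profile == "full") {
    list(rollout_steps = 50000L, driving = 20000L, search = 30000L,
         supervisory = 20000L, calibration_trials = 30L)
  } else {
    list(rollout_steps = 20000L, driving = 8000L, search = 10000L,
         supervisory = 2000L, calibration_trials = 20L)
  }
}
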