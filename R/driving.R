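#' Lane-keeping dynamics, belief tracking and reward
#'
#' The driving task is a POMDP over the car's lateral position in the lane.
#' The true state is continuous (`lateral_offset` in metres plus a bounded
#' dimensionless steering state); the agent reasons over `n_position_bins`
#' discretized positions through a belief distribution updated by Bayes'
#' rule from a learned stochastic transition model and noisy position
#' observations.
#'
#' @name driving
NULL

#' Create a driving state
#'
#' @param lateral_offset_m Signed lateral offset from the centre of the
#'   centre lane, metres.
#' @param steering Dimensionless steering state, within the configured
#'   steering range.
#' @param params A [driving_params()] object.
#' @return A `driving_state` list.
#' @export
driving_state <- function(lateral_offset_m = 0, steering = 0,
                          params = driving_params()) {
  if (!is.finite(lateral_offset_m)) abort("`lateral_offset_m` must be finite.")
  if (abs(steering) > params$steering_max + 1e-12) {
    abort("`steering` outside the configured steering range.")
  }
  structure(list(lateral_offset_m = lateral_offset_m, steering = steering,
                 speed_kmh = params$speed_kmh),
            class = "driving_state")
}

# offset -> discretized bin (1-based); out-of-range offsets clamp to edges
offset_to_bin <- function(offset, params) {
  b <- floor((offset + params$offset_range_m) / params$bin_width_m) + 1
  as.integer(clip(b, 1L, params$n_position_bins))
}

# steering value -> index into params$steering_values
steering_to_index <- function(steering, params) {
  as.integer(round((steering + params$steering_max) / params$steering_step)) + 1L
}

#' Advance the true driving state by one cycle
#'
#' `steering' = clip(steering + action)`;
#' `offset' = offset + v * duration * steering' + drift * duration + noise`,
#' where the noise is Gaussian with standard deviation
#' `sigma_d * sqrt(duration / dt_drive_s)` so that composing sub-steps of a
#' cycle accumulates the same noise variance as one full cycle.
#'
#' @param state A [driving_state()].
#' @param action A steering adjustment; must be an element of
#'   `params$action_set`.
#' @param params A [driving_params()] object.
#' @param duration Step duration in seconds (defaults to one driving cycle).
#' @return The next `driving_state`.
#' @examples
#' p <- driving_params(sigma_d = 0, curvature_drift_mps = 0)
#' s <- simulate_step(driving_state(0, 0, p), 0.01, p)
#' s$lateral_offset_m  # 16.667 m/s * 0.25 s * 0.01
#' @export
simulate_step <- function(state, action, params, duration = params$dt_drive_s) {
  if (!any(abs(params$action_set - action) < 1e-12)) {
    abort(sprintf("steering action %g is not in the configured action set", action))
  }
  steering <- clip(state$steering + action, -params$steering_max, params$steering_max)
  noise_sd <- params$sigma_d * sqrt(duration / params$dt_drive_s)
  noise <- if (noise_sd > 0) rnorm(1, 0, noise_sd) else 0
  offset <- state$lateral_offset_m +
    params$speed_mps * duration * steering +
    params$curvature_drift_mps * duration +
    noise
  structure(list(lateral_offset_m = offset, steering = steering,
                 speed_kmh = state$speed_kmh),
            class = "driving_state")
}

#' Driving reward
#'
#' A negative reward accrues while the car is beyond the lane bound; the
#' reward is 0 within it (closed interval: exactly on the bound is safe).
#'
#' @param state A [driving_state()].
#' @param params A [driving_params()] object.
#' @param duration Seconds spent in this state.
#' @return `0` inside the lane bound, else `-penalty_rate * duration`.
#' @export
driving_reward <- function(state, params, duration = params$dt_drive_s) {
  if (duration <= 0) abort("`duration` must be > 0.")
  if (abs(state$lateral_offset_m) <= params$lane_half_bound_m) 0
  else -params$penalty_rate * duration
}

#' Learn the stochastic driving transition model
#'
#' Performs `n_rollout_steps` random-action steps of the true dynamics,
#' fully observing the outcomes, and tallies empirical next-bin frequencies
#' per (position bin, action). The rollout restarts periodically from a
#' uniform random offset and steering state so that all bins are visited.
#' Unvisited (bin, action) cells fall back to a stay-in-bin prior with a
#' small diffusion `fallback_eps` to adjacent bins, preventing
#' zero-probability traps early in learning.
#'
#' Note the model conditions on the discretized position and action only:
#' the hidden steering state is marginalized out, so the learned model is a
#' deliberately coarse approximation of the true dynamics. Its extra
#' dispersion is what makes belief uncertainty grow quickly while driving
#' blind.
#'
#' @param params A [driving_params()] object.
#' @param n_rollout_steps Number of random-action training steps (>= 1).
#' @param fallback_eps Diffusion mass of the fallback prior.
#' @param restart_every Steps between uniform restarts.
#' @return A `transition_model` with the count array, the normalized
#'   probability array `prob` (`[from, action, to]`), and per-action
#'   transition matrices `M`.
#' @export
learn_transition_model <- function(params, n_rollout_steps = 20000,
                                   fallback_eps = 0.05, restart_every = 50) {
  if (n_rollout_steps < 1) abort("`n_rollout_steps` must be >= 1.")
  nb <- params$n_position_bins
  na <- length(params$action_set)
  counts <- array(0, dim = c(nb, na, nb))
  state <- driving_state(runif(1, -params$offset_range_m, params$offset_range_m),
                         sample(params$steering_values, 1), params)
  for (i in seq_len(n_rollout_steps)) {
    if (i %% restart_every == 0 || abs(state$lateral_offset_m) > params$offset_range_m) {
      state <- driving_state(runif(1, -params$offset_range_m, params$offset_range_m),
                             sample(params$steering_values, 1), params)
    }
    a <- sample.int(na, 1)
    from <- offset_to_bin(state$lateral_offset_m, params)
    state <- simulate_step(state, params$action_set[a], params)
    to <- offset_to_bin(state$lateral_offset_m, params)
    counts[from, a, to] <- counts[from, a, to] + 1
  }
  normalize_transition_model(counts, params, fallback_eps)
}

# counts array -> transition_model with normalized rows and fallback prior
normalize_transition_model <- function(counts, params, fallback_eps = 0.05) {
  nb <- dim(counts)[1]; na <- dim(counts)[2]
  prob <- array(0, dim = dim(counts))
  for (a in seq_len(na)) {
    for (s in seq_len(nb)) {
      n <- sum(counts[s, a, ])
      if (n > 0) {
        prob[s, a, ] <- counts[s, a, ] / n
      } else {
        row <- numeric(nb)
        nbrs <- intersect(c(s - 1, s + 1), seq_len(nb))
        row[s] <- 1 - fallback_eps
        row[nbrs] <- fallback_eps / length(nbrs)
        prob[s, a, ] <- row
      }
    }
  }
  M <- lapply(seq_len(na), function(a) prob[, a, , drop = TRUE])
  structure(list(counts = counts, prob = prob, M = M,
                 n_bins = nb, n_actions = na,
                 fallback_eps = fallback_eps),
            class = "transition_model")
}

#' Uniform prior belief over lane positions
#' @param params A [driving_params()] object.
#' @return Probability vector of length `n_position_bins`.
#' @export
uniform_belief <- function(params) {
  rep(1 / params$n_position_bins, params$n_position_bins)
}

#' Point-mass belief at a bin
#' @param bin Bin index.
#' @param params A [driving_params()] object.
#' @return Probability vector.
#' @export
point_belief <- function(bin, params) {
  b <- numeric(params$n_position_bins)
  b[bin] <- 1
  b
}

#' Prior-predictive belief update (blind driving step)
#'
#' Pushes the belief through the learned transition model for one action:
#' `b_pred(s') = sum_s tau_d(s, a, s') b(s)`. This is the whole update when
#' attention is off the road and no lane-position observation arrives.
#'
#' @param belief Probability vector over position bins.
#' @param action_index Index into the action set.
#' @param tau A `transition_model`.
#' @return The predicted belief (sums to 1).
#' @export
belief_predict <- function(belief, action_index, tau) {
  b <- as.vector(belief %*% tau$M[[action_index]])
  s <- sum(b)
  if (s <= 0) return(rep(1 / length(b), length(b)))
  b / s
}

#' Bayesian correction of a predicted belief by an observation
#'
#' The observation likelihood places `p_obs_correct` on the observed bin
#' and spreads the remainder uniformly over the other bins; the posterior
#' is `likelihood * predicted`, renormalized. A zero normalizer (an
#' observation impossible under a degenerate predicted belief) resets the
#' posterior to the normalized likelihood itself.
#'
#' @param predicted Predicted belief vector.
#' @param observation Observed bin index.
#' @param params A [driving_params()] object.
#' @return The posterior belief.
#' @export
belief_correct <- function(predicted, observation, params) {
  nb <- params$n_position_bins
  if (observation < 1 || observation > nb) abort("`observation` is not a valid bin.")
  lik <- rep((1 - params$p_obs_correct) / (nb - 1), nb)
  lik[observation] <- params$p_obs_correct
  post <- lik * predicted
  z <- sum(post)
  if (z <= 0) {
    warn("impossible observation under a degenerate belief; resetting to likelihood")
    return(lik / sum(lik))
  }
  post / z
}

#' Sufficient statistic of a driving belief
#'
#' Compresses the belief to its most likely position (argmax, ties to the
#' lowest index) and Shannon entropy in nats (`0 * log 0 = 0`), the
#' statistic over which the tabular driving policy is learned.
#'
#' @param belief Probability vector.
#' @return List with `map_position` (bin index) and `entropy` (nats).
#' @examples
#' belief_summary(rep(0.1, 10))$entropy  # log(10)
#' @export
belief_summary <- function(belief) {
  nz <- belief[belief > 0]
  list(map_position = which.max(belief),
       entropy = -sum(nz * log(nz)))
}

# sample a noisy observation of the true bin
sample_observation <- function(true_bin, params) {
  nb <- params$n_position_bins
  if (runif(1) < params$p_obs_correct) true_bin
  else sample(setdiff(seq_len(nb), true_bin), 1)
}

# entropy (nats) -> bin index in 1..n_entropy_bins over [0, log(n_bins)]
entropy_to_bin <- function(entropy, params) {
  w <- log(params$n_position_bins) / params$n_entropy_bins
  as.integer(clip(floor(entropy / w) + 1, 1L, params$n_entropy_bins))
}

# (map bin, entropy bin, steering index) -> flat tabular state index
driving_state_index <- function(map_bin, ent_bin, steer_idx, params) {
  nb <- params$n_position_bins
  ne <- params$n_entropy_bins
  map_bin + (ent_bin - 1L) * nb + (steer_idx - 1L) * nb * ne
}

n_driving_states <- function(params) {
  params$n_position_bins * params$n_entropy_bins * length(params$steering_values)
}

#' Tabular learning environment for the driving task
#'
#' Wraps the driving POMDP behind the reset/step contract used by
#' [train_policy()]. An episode is `episode_steps` driving cycles from the
#' lane centre. With `observe = "always"` a lane-position observation is
#' incorporated every cycle (the fully attended setting). With
#' `observe = "intermittent"` (the default used by the training pipeline)
#' observations occasionally drop out in short blind stretches, emulating
#' the glances away from the road that the policy will experience under the
#' supervisory model, so that high-entropy belief states acquire Q-values.
#'
#' @param params A [driving_params()] object.
#' @param tau A learned `transition_model`.
#' @param episode_steps Cycles per training episode.
#' @param observe `"intermittent"` or `"always"`.
#' @param blind_start_prob Per-cycle probability of starting a blind
#'   stretch (intermittent mode).
#' @param blind_mean_len Mean length, in cycles, of a blind stretch
#'   (geometric).
#' @return An environment object for [train_policy()].
#' @export
make_driving_env <- function(params, tau, episode_steps = 100,
                             observe = c("intermittent", "always"),
                             blind_start_prob = 0.1, blind_mean_len = 8) {
  observe <- match.arg(observe)
  e <- new.env(parent = emptyenv())
  e$n_states <- n_driving_states(params)
  e$n_actions <- length(params$action_set)
  e$params <- params

  # hoisted constants for the hot loop
  nb <- params$n_position_bins
  ne <- params$n_entropy_bins
  actions <- params$action_set
  smax <- params$steering_max
  inv_sstep <- 1 / params$steering_step
  v_dt <- params$speed_mps * params$dt_drive_s
  drift_dt <- params$curvature_drift_mps * params$dt_drive_s
  sigma <- params$sigma_d
  inv_bw <- 1 / params$bin_width_m
  half_range <- params$offset_range_m
  bound <- params$lane_half_bound_m
  penalty <- params$penalty_rate * params$dt_drive_s
  p_obs <- params$p_obs_correct
  lik_other <- (1 - p_obs) / (nb - 1)
  ent_w <- log(nb) / ne
  M <- tau$M
  intermittent <- observe == "intermittent"

  to_bin <- function(x) {
    b <- floor((x + half_range) * inv_bw) + 1
    if (b < 1) 1L else if (b > nb) nb else as.integer(b)
  }
  state_index <- function() {
    b <- e$belief
    nz <- b[b > 0]
    ent <- -sum(nz * log(nz))
    eb <- floor(ent / ent_w) + 1
    if (eb > ne) eb <- ne
    si <- as.integer(round((e$steering + smax) * inv_sstep)) + 1L
    which.max(b) + (as.integer(eb) - 1L) * nb + (si - 1L) * nb * ne
  }
  e$reset <- function() {
    e$offset <- 0
    e$steering <- 0
    e$state <- list(lateral_offset_m = 0, steering = 0)
    e$belief <- point_belief(to_bin(0), params)
    e$t <- 0L
    e$blind_left <- 0L
    state_index()
  }
  e$step <- function(a) {
    st <- e$steering + actions[a]
    if (st > smax) st <- smax else if (st < -smax) st <- -smax
    off <- e$offset + v_dt * st + drift_dt + rnorm(1, 0, sigma)
    e$steering <- st
    e$offset <- off
    e$state <- list(lateral_offset_m = off, steering = st)
    b <- as.vector(e$belief %*% M[[a]])
    b <- b / sum(b)
    blind <- FALSE
    if (intermittent) {
      if (e$blind_left > 0L) {
        e$blind_left <- e$blind_left - 1L
        blind <- TRUE
      } else if (runif(1) < blind_start_prob) {
        e$blind_left <- rgeom_len(blind_mean_len)
        blind <- TRUE
      }
    }
    if (!blind) {
      true_bin <- to_bin(off)
      obs <- if (runif(1) < p_obs) true_bin else {
        o <- sample.int(nb - 1L, 1L)
        if (o >= true_bin) o + 1L else o
      }
      post <- b * lik_other
      post[obs] <- b[obs] * p_obs
      z <- sum(post)
      b <- if (z > 0) post / z else {
        lik <- rep(lik_other, nb); lik[obs] <- p_obs; lik / sum(lik)
      }
    }
    e$belief <- b
    e$t <- e$t + 1L
    list(state = state_index(),
         reward = if (off >= -bound && off <= bound) 0 else -penalty,
         done = e$t >= episode_steps)
  }
  class(e) <- c("driving_env", "rl_env")
  e
}

# geometric blind-stretch length with the given mean, at least 1
rgeom_len <- function(mean_len) {
  1L + stats::rgeom(1, 1 / mean_len)
}

#' Evaluate a driving policy (or the uniform-random baseline)
#'
#' Runs seeded episodes of attended driving and reports per-episode lane
#' keeping quality. With `qtable = NULL` actions are uniform random.
#'
#' @param params A [driving_params()] object.
#' @param tau A learned `transition_model` (for belief tracking).
#' @param qtable Trained driving `qtable`, or `NULL` for the random
#'   baseline.
#' @param n_episodes,episode_steps Evaluation size.
#' @param tau_sm Softmax temperature used with a trained table.
#' @return Tibble with per-episode `mean_abs_offset`, `n_out_of_bounds`,
#'   `return` and belief-tracking accuracy `map_match_rate`.
#' @export
evaluate_driving_policy <- function(params, tau, qtable = NULL,
                                    n_episodes = 100, episode_steps = 100,
                                    tau_sm = 0.05) {
  env <- make_driving_env(params, tau, episode_steps = episode_steps,
                          observe = "always")
  purrr::map_dfr(seq_len(n_episodes), function(ep) {
    env$reset()
    abs_off <- numeric(episode_steps)
    oob <- 0L
    ret <- 0
    match <- 0L
    for (i in seq_len(episode_steps)) {
      a <- if (is.null(qtable)) sample.int(env$n_actions, 1)
           else select_action(qtable, local_state_index(env), tau_sm)
      out <- env$step(a)
      abs_off[i] <- abs(env$state$lateral_offset_m)
      if (abs_off[i] > params$lane_half_bound_m) oob <- oob + 1L
      ret <- ret + out$reward
      if (belief_summary(env$belief)$map_position ==
          offset_to_bin(env$state$lateral_offset_m, params)) match <- match + 1L
    }
    tibble::tibble(episode = ep, mean_abs_offset = mean(abs_off),
                   n_out_of_bounds = oob, return = ret,
                   map_match_rate = match / episode_steps)
  })
}

# current tabular state of a driving env (mirrors the env's internal key)
local_state_index <- function(env) {
  s <- belief_summary(env$belief)
  driving_state_index(s$map_position, entropy_to_bin(s$entropy, env$params),
                      steering_to_index(env$state$steering, env$params),
                      env$params)
}

#' Serialize a transition model to a data frame
#' @param tau A `transition_model`.
#' @return Tibble with columns `from_bin`, `action_index`, `to_bin`,
#'   `probability`.
#' @export
transition_model_df <- function(tau) {
  g <- expand.grid(from_bin = seq_len(tau$n_bins),
                   action_index = seq_len(tau$n_actions),
                   to_bin = seq_len(tau$n_bins))
  g$probability <- tau$prob[as.matrix(g)]
  tibble::as_tibble(g[g$probability > 0, ])
}

#' Rebuild a transition model from its data-frame serialization
#' @param df Output of [transition_model_df()].
#' @param params A [driving_params()] object.
#' @return A `transition_model`.
#' @export
transition_model_from_df <- function(df, params) {
  nb <- params$n_position_bins
  na <- length(params$action_set)
  prob <- array(0, dim = c(nb, na, nb))
  prob[cbind(df$from_bin, df$action_index, df$to_bin)] <- df$probability
  M <- lapply(seq_len(na), function(a) prob[, a, , drop = TRUE])
  structure(list(counts = NULL, prob = prob, M = M, n_bins = nb,
                 n_actions = na, fallback_eps = NA_real_),
            class = "transition_model")
}
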