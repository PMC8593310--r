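#' In-car visual search with EMMA eye-movement timing
#'
#' The in-car task is a POMDP over a small display of randomly placed
#' items, one of which may be the target. Each encode action fixates and
#' encodes one item; encoding and saccade durations follow the EMMA model.
#' The belief is the grid of items encoded so far plus the current fixation
#' location.
#'
#' @name search
NULL

#' Time to encode a visual object (EMMA)
#'
#' `T_e = K * (-log f) * exp(k * eccentricity)`, natural log. Rare objects
#' (small `f`) and peripheral objects (large eccentricity) take longer.
#'
#' @param f Object frequency in `(0, 1]`.
#' @param eccentricity_deg Angular distance from the current fixation,
#'   degrees (>= 0).
#' @param params A [search_params()] object (supplies `K` and `k`).
#' @return Encoding time in seconds.
#' @examples
#' encoding_time(0.01, 5, search_params())  # about 0.204 s
#' @export
encoding_time <- function(f, eccentricity_deg, params) {
  if (f <= 0 || f > 1) abort("`f` must be in (0, 1].")
  if (eccentricity_deg < 0) abort("`eccentricity_deg` must be >= 0.")
  params$K * (-log(f)) * exp(params$k * eccentricity_deg)
}

#' Saccade duration (EMMA)
#'
#' `T_s = t_prep + t_exec + D * t_sacc`: fixed preparation and execution
#' components plus travel time proportional to the distance covered.
#'
#' @param distance_deg Saccade amplitude in degrees (>= 0).
#' @param params A [search_params()] object.
#' @return Saccade duration in seconds.
#' @examples
#' saccade_time(34, search_params())  # 0.273 s, the road-to-display hop
#' @export
saccade_time <- function(distance_deg, params) {
  if (distance_deg < 0) abort("`distance_deg` must be >= 0.")
  params$t_prep + params$t_exec + distance_deg * params$t_sacc
}

#' Generate a random search display
#'
#' Items are rejection-sampled uniformly over the display extent until all
#' pairwise separations are at least `min_separation_deg`. The initial
#' fixation is the display entry point (top-centre), where the eyes land
#' coming from the road.
#'
#' @param params A [search_params()] object.
#' @param target_present If `TRUE` one item, chosen uniformly, is the
#'   target; otherwise the screen is a foil (target absent).
#' @param max_attempts Rejection-sampling budget before the display is
#'   declared too small.
#' @return A `search_state` list: `item_positions` (n x 2 matrix, degrees),
#'   `target_index` (or `NA` for a foil), and `fixation`.
#' @export
generate_layout <- function(params, target_present = TRUE, max_attempts = 10000) {
  n <- params$n_items
  pos <- matrix(NA_real_, n, 2)
  placed <- 0L
  attempts <- 0L
  hx <- params$extent_x_deg / 2
  hy <- params$extent_y_deg / 2
  while (placed < n) {
    attempts <- attempts + 1L
    if (attempts > max_attempts) {
      abort("could not place items at the required separation; display too small")
    }
    cand <- c(runif(1, -hx, hx), runif(1, -hy, hy))
    ok <- placed == 0L ||
      all(sqrt((pos[seq_len(placed), 1] - cand[1])^2 +
               (pos[seq_len(placed), 2] - cand[2])^2) >= params$min_separation_deg)
    if (ok) {
      placed <- placed + 1L
      pos[placed, ] <- cand
    }
  }
  structure(list(
    item_positions = pos,
    target_index = if (target_present) sample.int(n, 1) else NA_integer_,
    fixation = params$entry_fixation
  ), class = "search_state")
}

#' Empty search belief for a display
#' @param state A `search_state`.
#' @return A `search_belief`: per-item encoded flags (all `FALSE`), known
#'   identities, and the fixation location.
#' @export
empty_search_belief <- function(state) {
  n <- nrow(state$item_positions)
  structure(list(encoded = rep(FALSE, n),
                 is_target = rep(NA, n),
                 fixation = state$fixation),
            class = "search_belief")
}

#' Encode one item, with EMMA timing
#'
#' If the encoding time at the item's current eccentricity is below the
#' saccade preparation time, the item is encoded covertly without moving
#' the eyes. Otherwise a saccade brings the fixation to the item and the
#' remaining fraction of the encoding is completed there at zero
#' eccentricity: `elapsed = T_s + (1 - min(1, T_s / T_e)) * T_e(0)`.
#' Re-encoding an already-encoded item is permitted (it wastes time;
#' policies learn to avoid it).
#'
#' @param state A `search_state`.
#' @param belief A `search_belief`.
#' @param item Item index to encode.
#' @param params A [search_params()] object.
#' @return List with the updated `belief` (item marked encoded, fixation
#'   possibly moved), `elapsed` seconds, and `saccade` flag.
#' @export
encode_action <- function(state, belief, item, params) {
  n <- nrow(state$item_positions)
  if (item < 1 || item > n) abort("`item` is not a valid item index.")
  p <- state$item_positions[item, ]
  eps <- sqrt(sum((belief$fixation - p)^2))
  te <- encoding_time(params$f, eps, params)
  if (te < params$t_prep) {
    elapsed <- te
    saccade <- FALSE
  } else {
    ts <- saccade_time(eps, params)
    completed <- min(1, ts / te)
    elapsed <- ts + (1 - completed) * encoding_time(params$f, 0, params)
    belief$fixation <- p
    saccade <- TRUE
  }
  belief$encoded[item] <- TRUE
  belief$is_target[item] <- identical(item, state$target_index) ||
    (!is.na(state$target_index) && item == state$target_index)
  list(belief = belief, elapsed = elapsed, saccade = saccade)
}

#' Search reward
#'
#' The time cost of the encode is charged as a negative reward; completing
#' the trial adds the large positive completion reward.
#'
#' @param elapsed Seconds spent on the encode (>= 0).
#' @param trial_done Whether this encode completed the trial.
#' @param params A [search_params()] object.
#' @param foil Whether the screen is a foil (uses `reward_foil_done`).
#' @return Numeric reward.
#' @export
search_reward <- function(elapsed, trial_done, params, foil = FALSE) {
  if (elapsed < 0) abort("`elapsed` must be >= 0.")
  bonus <- if (!trial_done) 0 else if (foil) params$reward_foil_done else params$reward_found
  -elapsed + bonus
}

#' Is the search trial complete?
#'
#' Target-present screens complete when the target has been encoded;
#' foil screens complete when every item has been encoded.
#'
#' @param state A `search_state`.
#' @param belief A `search_belief`.
#' @return Logical flag.
#' @export
is_trial_complete <- function(state, belief) {
  if (!is.na(state$target_index)) belief$encoded[state$target_index]
  else all(belief$encoded)
}

# --- coarse 3x3 cell partition used as the tabular policy state ------------

n_search_cells <- function() 9L

# (x, y) in degrees -> cell index 1..9 (column-major over a 3x3 grid)
cell_of <- function(xy, params) {
  ix <- as.integer(clip(floor((xy[1] + params$extent_x_deg / 2) /
                                (params$extent_x_deg / 3)) + 1, 1L, 3L))
  iy <- as.integer(clip(floor((xy[2] + params$extent_y_deg / 2) /
                                (params$extent_y_deg / 3)) + 1, 1L, 3L))
  ix + (iy - 1L) * 3L
}

cell_center <- function(cell, params) {
  ix <- (cell - 1L) %% 3L + 1L
  iy <- (cell - 1L) %/% 3L + 1L
  c(-params$extent_x_deg / 2 + (ix - 0.5) * params$extent_x_deg / 3,
    -params$extent_y_deg / 2 + (iy - 0.5) * params$extent_y_deg / 3)
}

# per-item cell indices for a layout
layout_cells <- function(state, params) {
  vapply(seq_len(nrow(state$item_positions)),
         function(i) cell_of(state$item_positions[i, ], params), integer(1))
}

# 9-bit "cell cleared" pattern: a cell is cleared when it holds no
# unencoded item (empty cells count as cleared)
cell_pattern <- function(cells, encoded) {
  bits <- 0L
  for (c in 1:9) {
    if (!any(cells == c & !encoded)) bits <- bits + bitwShiftL(1L, c - 1L)
  }
  bits
}

search_state_index <- function(fix_cell, pattern) {
  fix_cell + 9L * pattern
}

n_search_states <- function() 9L * 512L

#' Tabular learning environment for the visual-search task
#'
#' Wraps the search POMDP behind the reset/step contract of
#' [train_policy()]. The policy state is the current fixation cell of a
#' coarse 3x3 partition of the display plus the 9-bit pattern of cells
#' already cleared of unencoded items; the 9 actions aim the next encode at
#' a cell. Aiming at a cell with unencoded items encodes the one nearest
#' the fixation; aiming at a cleared, non-empty cell re-encodes its nearest
#' item (wasted time); aiming at an empty cell saccades to the cell centre
#' and encodes nothing (also wasted). Episodes alternate target-present and
#' foil screens at the given rate.
#'
#' @param params A [search_params()] object.
#' @param p_target Probability a training screen is target-present.
#' @return An environment object for [train_policy()].
#' @export
make_search_env <- function(params, p_target = 0.5) {
  e <- new.env(parent = emptyenv())
  e$n_states <- n_search_states()
  e$n_actions <- n_search_cells()
  e$params <- params

  state_index <- function() {
    search_state_index(cell_of(e$belief$fixation, params),
                       cell_pattern(e$cells, e$belief$encoded))
  }
  e$reset <- function() {
    e$state <- generate_layout(params, target_present = runif(1) < p_target)
    e$belief <- empty_search_belief(e$state)
    e$cells <- layout_cells(e$state, params)
    e$t <- 0L
    state_index()
  }
  e$step <- function(a) {
    res <- search_env_act(e, a)
    e$t <- e$t + 1L
    done <- res$done || e$t >= params$max_episode_steps
    list(state = state_index(), reward = res$reward, done = done)
  }
  class(e) <- c("search_env", "rl_env")
  e
}

# perform one cell-directed action on a search env's mutable state;
# shared between training episodes and supervisory simulation
search_env_act <- function(e, a) {
  params <- e$params
  in_cell <- which(e$cells == a)
  unenc <- in_cell[!e$belief$encoded[in_cell]]
  if (length(unenc) > 0) {
    d <- sqrt((e$state$item_positions[unenc, 1] - e$belief$fixation[1])^2 +
              (e$state$item_positions[unenc, 2] - e$belief$fixation[2])^2)
    item <- unenc[which.min(d)]
  } else if (length(in_cell) > 0) {
    d <- sqrt((e$state$item_positions[in_cell, 1] - e$belief$fixation[1])^2 +
              (e$state$item_positions[in_cell, 2] - e$belief$fixation[2])^2)
    item <- in_cell[which.min(d)]
  } else {
    # empty cell: a fruitless saccade to its centre
    ctr <- cell_center(a, params)
    dist <- sqrt(sum((e$belief$fixation - ctr)^2))
    elapsed <- saccade_time(dist, params)
    e$belief$fixation <- ctr
    return(list(reward = -elapsed, elapsed = elapsed, item = NA_integer_,
                done = FALSE))
  }
  res <- encode_action(e$state, e$belief, item, params)
  e$belief <- res$belief
  done <- is_trial_complete(e$state, e$belief)
  foil <- is.na(e$state$target_index)
  list(reward = search_reward(res$elapsed, done, params, foil = foil),
       elapsed = res$elapsed, item = item, done = done)
}

#' Evaluate a search policy (or the uniform-random baseline)
#'
#' Runs seeded foil (or target-present) screens to completion and reports
#' per-trial encode counts and times. With `qtable = NULL` actions are
#' uniform random over cells.
#'
#' @param params A [search_params()] object.
#' @param qtable Trained search `qtable`, or `NULL` for the random
#'   baseline.
#' @param n_trials Number of screens.
#' @param target_present Screen type to evaluate.
#' @param tau_sm Softmax temperature used with a trained table.
#' @return Tibble with per-trial `n_encodes`, `search_time`, `return` and
#'   `completed`.
#' @export
evaluate_search_policy <- function(params, qtable = NULL, n_trials = 200,
                                   target_present = FALSE, tau_sm = 0.05) {
  env <- make_search_env(params, p_target = if (target_present) 1 else 0)
  purrr::map_dfr(seq_len(n_trials), function(tr) {
    s <- env$reset()
    n_enc <- 0L
    time <- 0
    ret <- 0
    done <- FALSE
    while (!done && n_enc < params$max_episode_steps) {
      a <- if (is.null(qtable)) sample.int(env$n_actions, 1)
           else select_action(qtable, s, tau_sm)
      res <- search_env_act(env, a)
      n_enc <- n_enc + 1L
      time <- time + res$elapsed
      ret <- ret + res$reward
      done <- res$done
      s <- search_state_index(cell_of(env$belief$fixation, params),
                              cell_pattern(env$cells, env$belief$encoded))
    }
    tibble::tibble(trial = tr, n_encodes = n_enc, search_time = time,
                   return = ret, completed = done)
  })
}
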