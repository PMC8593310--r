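#' Tabular SARSA with softmax action selection
#'
#' Shared learning machinery for the driving, search and supervisory
#' policies: a dense Q-table over discretized states, the on-policy SARSA
#' update, and Boltzmann (softmax) exploration.
#'
#' @name rl_core
NULL

#' Create an empty Q-table
#'
#' States the learner has never visited keep their initial utility of 0.
#'
#' @param n_states,n_actions Table dimensions.
#' @param q_init Initial utility for every state-action cell. 0 by default
#'   (and 0, the best attainable return, is already optimistic for a task
#'   whose rewards are all non-positive); for tasks with a large positive
#'   terminal reward, initializing at that reward gives classic optimistic
#'   initialization, which drives systematic exploration of untried
#'   actions and prevents on-policy lock-in on wasteful action cycles.
#' @param state_labeller Optional function mapping a state index to a
#'   human-readable key for serialization.
#' @return A `qtable` object.
#' @export
new_qtable <- function(n_states, n_actions, q_init = 0, state_labeller = NULL) {
  structure(list(q = matrix(q_init, n_states, n_actions),
                 n_states = as.integer(n_states),
                 n_actions = as.integer(n_actions),
                 visits = integer(n_states),
                 state_labeller = state_labeller),
            class = "qtable")
}

# annealed softmax temperature for episode `ep`: linear from tau_start to
# tau_end over the first anneal_frac of episodes, then held
anneal_temperature <- function(ep, lp) {
  n_anneal <- max(1, floor((lp$anneal_frac %||% 1) * lp$n_episodes))
  if (n_anneal <= 1) return(lp$tau_end)
  frac <- min(1, (ep - 1) / (n_anneal - 1))
  lp$tau_start + (lp$tau_end - lp$tau_start) * frac
}

#' One SARSA update
#'
#' `Q(s,a) <- Q(s,a) + alpha * (r + gamma * Q(s',a') - Q(s,a))`.
#'
#' @param q_sa Current utility `Q(s,a)`.
#' @param r Observed reward.
#' @param q_s2a2 Utility of the successor state-action `Q(s',a')` (0 at a
#'   terminal state).
#' @param alpha Learning rate.
#' @param gamma Discount factor.
#' @return The updated utility.
#' @examples
#' sarsa_update(0, 1, 0, alpha = 0.1, gamma = 0.9)  # 0.1
#' @export
sarsa_update <- function(q_sa, r, q_s2a2, alpha, gamma) {
  if (!all(is.finite(c(q_sa, r, q_s2a2, alpha, gamma)))) {
    abort("non-finite input to sarsa_update()")
  }
  q_sa + alpha * (r + gamma * q_s2a2 - q_sa)
}

#' Softmax (Boltzmann) action probabilities
#'
#' `p(a) = exp(Q(s,a)/tau) / sum_i exp(Q(s,i)/tau)`, computed with
#' max-subtraction for overflow safety (numerically identical by shift
#' invariance).
#'
#' @param q_values Utility vector for one state.
#' @param tau_sm Temperature, > 0; small values approach greedy selection.
#' @return Probability vector (positive, sums to 1).
#' @examples
#' softmax_probs(c(1, 0), 1)  # c(e, 1) / (1 + e)
#' @export
softmax_probs <- function(q_values, tau_sm) {
  if (tau_sm <= 0) abort("`tau_sm` must be > 0.")
  z <- q_values / tau_sm
  z <- z - max(z)
  ez <- exp(z)
  ez / sum(ez)
}

#' Sample an action from the softmax policy at a state
#'
#' Unseen states hold the zero utility vector, so selection there is
#' uniform.
#'
#' @param qtable A [new_qtable()] object.
#' @param state State index.
#' @param tau_sm Softmax temperature.
#' @return An action index.
#' @export
select_action <- function(qtable, state, tau_sm) {
  sample_softmax(qtable$q[state, ], tau_sm)
}

# draw one action index from the softmax distribution (hot path: avoids
# sample.int's probability preprocessing)
sample_softmax <- function(q_values, tau_sm) {
  z <- q_values / tau_sm
  ez <- exp(z - max(z))
  cs <- cumsum(ez)
  min(length(q_values), sum(runif(1) * cs[length(cs)] > cs) + 1L)
}

#' Utility of the best available action at a state
#'
#' @param qtable A [new_qtable()] object.
#' @param state State index.
#' @return `max_a Q(state, a)`; 0 for unseen states.
#' @export
max_q <- function(qtable, state) {
  max(qtable$q[state, ])
}

#' Train a tabular policy by SARSA with annealed softmax exploration
#'
#' Runs `n_episodes` episodes against an environment exposing `reset()`
#' (returning an initial state index), `step(action)` (returning
#' `list(state, reward, done)`), `n_states` and `n_actions`. The softmax
#' temperature anneals linearly from `tau_start` to `tau_end` across
#' episodes. Training aborts with a diagnostic if the Q-table diverges to
#' non-finite values.
#'
#' @param env An environment from [make_driving_env()], [make_search_env()]
#'   or a compatible object.
#' @param lp A [learning_params()] object.
#' @param qtable Optional Q-table to continue training; a fresh table at
#'   `q_init` by default.
#' @param q_init Initial utility for a fresh table (see [new_qtable()]).
#' @param max_steps Per-episode step cap (guards non-terminating
#'   environments).
#' @return List with the trained `qtable` and a per-episode `log` tibble
#'   (`episode`, `return`, `steps`, `tau`).
#' @export
train_policy <- function(env, lp, qtable = NULL, q_init = 0, max_steps = 1000) {
  if (is.null(qtable)) qtable <- new_qtable(env$n_states, env$n_actions, q_init)
  n_ep <- lp$n_episodes
  log_return <- numeric(n_ep)
  log_steps <- integer(n_ep)
  log_tau <- numeric(n_ep)
  q <- qtable$q
  visits <- qtable$visits
  nsa <- matrix(0L, env$n_states, env$n_actions)
  alpha0 <- lp$alpha; adec <- lp$alpha_decay %||% 0; gamma <- lp$gamma
  for (ep in seq_len(n_ep)) {
    tau <- anneal_temperature(ep, lp)
    s <- env$reset()
    a <- sample_softmax(q[s, ], tau)
    ret <- 0
    steps <- 0L
    repeat {
      out <- env$step(a)
      r <- out$reward
      ret <- ret + r
      steps <- steps + 1L
      visits[s] <- visits[s] + 1L
      alpha <- alpha0 / (1 + adec * nsa[s, a])
      nsa[s, a] <- nsa[s, a] + 1L
      if (out$done || steps >= max_steps) {
        q[s, a] <- q[s, a] + alpha * (r - q[s, a])
        break
      }
      s2 <- out$state
      a2 <- sample_softmax(q[s2, ], tau)
      q[s, a] <- q[s, a] + alpha * (r + gamma * q[s2, a2] - q[s, a])
      s <- s2; a <- a2
    }
    if (!all(is.finite(q[s, ]))) {
      abort(sprintf("Q-table diverged to non-finite values at episode %d", ep))
    }
    log_return[ep] <- ret
    log_steps[ep] <- steps
    log_tau[ep] <- tau
  }
  qtable$q <- q
  qtable$visits <- visits
  list(qtable = qtable,
       log = tibble::tibble(episode = seq_len(n_ep), return = log_return,
                            steps = log_steps, tau = log_tau))
}

#' @export
print.qtable <- function(x, ...) {
  cat(sprintf("<qtable> %d states x %d actions; %d states visited\n",
              x$n_states, x$n_actions, sum(x$visits > 0)))
  invisible(x)
}

#' Tidy a Q-table into a long tibble
#'
#' @param x A `qtable`.
#' @param all Include never-visited (all-zero) states too.
#' @param ... Unused.
#' @return Tibble with `state_key`, `action_index`, `q_value`.
#' @importFrom generics tidy
#' @export
tidy.qtable <- function(x, all = FALSE, ...) {
  keep <- if (all) seq_len(x$n_states) else which(x$visits > 0)
  labs <- if (is.null(x$state_labeller)) as.character(keep)
          else vapply(keep, x$state_labeller, character(1))
  tibble::tibble(
    state_key = rep(labs, each = x$n_actions),
    state_index = rep(keep, each = x$n_actions),
    action_index = rep(seq_len(x$n_actions), times = length(keep)),
    q_value = as.vector(t(x$q[keep, , drop = FALSE]))
  )
}

#' One-row summary of a Q-table
#'
#' @param x A `qtable`.
#' @param ... Unused.
#' @return Tibble with state/action counts and the utility range.
#' @importFrom generics glance
#' @export
glance.qtable <- function(x, ...) {
  tibble::tibble(n_states = x$n_states, n_actions = x$n_actions,
                 n_visited = sum(x$visits > 0),
                 q_min = min(x$q), q_max = max(x$q))
}

#' @export
generics::tidy

#' @export
generics::glance

#' Write / read a Q-table as CSV
#'
#' @param qtable A `qtable`.
#' @param path File path.
#' @return `read_qtable()` returns a `qtable` (visit counts are not
#'   preserved; serialized states are marked visited).
#' @export
write_qtable <- function(qtable, path) {
  df <- tidy(qtable)
  utils::write.csv(df[c("state_index", "action_index", "q_value")], path,
                   row.names = FALSE)
  invisible(path)
}

#' @rdname write_qtable
#' @param n_states,n_actions Dimensions of the table being restored.
#' @export
read_qtable <- function(path, n_states, n_actions) {
  df <- utils::read.csv(path)
  qt <- new_qtable(n_states, n_actions)
  qt$q[cbind(df$state_index, df$action_index)] <- df$q_value
  qt$visits[unique(df$state_index)] <- 1L
  qt
}
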