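# Lane-keeping dynamics, belief tracking, reward and the driving learner.

test_that("simulate_step follows the stated deterministic dynamics", {
  p <- driving_params(speed_kmh = 60, sigma_d = 0, curvature_drift_mps = 0)
  s <- simulate_step(driving_state(0, 0, p), 0.01, p)
  expect_equal(s$steering, 0.01)
  expect_equal(s$lateral_offset_m, p$speed_mps * p$dt_drive_s * 0.01)

  # steering state saturates at the configured maximum
  s2 <- driving_state(0, p$steering_max, p)
  s3 <- simulate_step(s2, 0.02, p)
  expect_equal(s3$steering, p$steering_max)

  # the same steering moves the car twice as fast at twice the speed
  p2 <- driving_params(speed_kmh = 120, sigma_d = 0, curvature_drift_mps = 0)
  s4 <- simulate_step(driving_state(0, 0, p2), 0.01, p2)
  expect_equal(s4$lateral_offset_m, 2 * s$lateral_offset_m)

  expect_error(simulate_step(driving_state(0, 0, p), 0.005, p), "action")
})

test_that("sub-step noise composes to the full-cycle variance", {
  p <- driving_params(sigma_d = 0.05)
  set.seed(42)
  # two half-cycles accumulate the same variance as one full cycle
  n <- 20000
  half <- replicate(n, {
    s <- simulate_step(driving_state(0, 0, p), 0, p, duration = p$dt_drive_s / 2)
    s <- simulate_step(s, 0, p, duration = p$dt_drive_s / 2)
    s$lateral_offset_m
  })
  expect_equal(sd(half), p$sigma_d, tolerance = 0.05)
})

test_that("driving_reward penalizes only beyond the closed lane bound", {
  p <- driving_params()
  expect_identical(driving_reward(driving_state(0, 0, p), p), 0)
  expect_identical(driving_reward(driving_state(1.75, 0, p), p), 0)
  expect_equal(driving_reward(driving_state(2, 0, p), p, duration = 0.25), -0.25)
  expect_equal(driving_reward(driving_state(-2.3, 0, p), p, duration = 1), -1)
  expect_error(driving_reward(driving_state(0, 0, p), p, duration = 0), "duration")
})

test_that("learned transition model rows are distributions with fallback", {
  p <- driving_params()
  tau <- get_tau()
  sums <- apply(tau$prob, c(1, 2), sum)
  expect_true(all(abs(sums - 1) < 1e-9))
  expect_true(all(tau$prob >= 0))
  # unvisited rows fall back to stay-plus-diffusion
  tau0 <- learn_transition_model(p, n_rollout_steps = 1)
  row <- tau0$prob[10, 1, ]
  expect_equal(sum(row), 1, tolerance = 1e-12)
  expect_true(row[10] >= 1 - tau0$fallback_eps - 1e-12)
  expect_error(learn_transition_model(p, n_rollout_steps = 0), "n_rollout_steps")
})

test_that("transition model round-trips through its data frame form", {
  p <- driving_params()
  tau <- get_tau()
  df <- transition_model_df(tau)
  tau2 <- transition_model_from_df(df, p)
  expect_equal(tau2$prob, tau$prob)
  b <- runif(p$n_position_bins); b <- b / sum(b)
  expect_equal(belief_predict(b, 3, tau2), belief_predict(b, 3, tau))
})

test_that("belief_predict matches hand-computed push-forwards", {
  p3 <- driving_params(n_position_bins = 3)
  # deterministic shift-right model: bin i -> min(i + 1, 3)
  df <- tibble::tibble(from_bin = rep(1:3, times = length(p3$action_set)),
                       action_index = rep(seq_along(p3$action_set), each = 3),
                       to_bin = rep(c(2L, 3L, 3L), times = length(p3$action_set)),
                       probability = 1)
  tau_det <- transition_model_from_df(df, p3)
  expect_equal(belief_predict(c(1, 0, 0), 1, tau_det), c(0, 1, 0))

  # identity-with-epsilon-diffusion model, brute-force matrix product oracle
  eps <- 0.1
  M <- matrix(0, 3, 3)
  M[1, ] <- c(1 - eps, eps, 0)
  M[2, ] <- c(eps / 2, 1 - eps, eps / 2)
  M[3, ] <- c(0, eps, 1 - eps)
  df2 <- tibble::tibble(
    from_bin = rep(rep(1:3, each = 3), times = length(p3$action_set)),
    action_index = rep(seq_along(p3$action_set), each = 9),
    to_bin = rep(rep(1:3, times = 3), times = length(p3$action_set)),
    probability = rep(as.vector(t(M)), times = length(p3$action_set)))
  tau_eps <- transition_model_from_df(df2, p3)
  b <- c(0.5, 0.5, 0)
  expect_equal(belief_predict(b, 2, tau_eps), as.vector(b %*% M))

  # uniform belief through a doubly stochastic model stays uniform
  S <- matrix(1 / 3, 3, 3)
  df3 <- df2
  df3$probability <- rep(as.vector(t(S)), times = length(p3$action_set))
  tau_ds <- transition_model_from_df(df3, p3)
  expect_equal(belief_predict(rep(1 / 3, 3), 1, tau_ds), rep(1 / 3, 3))
})

test_that("belief_correct is the stated Bayes posterior", {
  # two-bin closed form: uniform prior, 0.9-correct observation of bin 1
  p2 <- list(n_position_bins = 2L, p_obs_correct = 0.9)
  expect_equal(belief_correct(c(0.5, 0.5), 1, p2), c(0.9, 0.1))

  p <- driving_params()
  b <- uniform_belief(p)
  post <- belief_correct(b, 11, p)
  expect_equal(sum(post), 1, tolerance = 1e-12)
  expect_equal(which.max(post), 11L)
  # brute-force oracle on a random prior
  set.seed(7)
  prior <- runif(p$n_position_bins); prior <- prior / sum(prior)
  lik <- rep((1 - p$p_obs_correct) / (p$n_position_bins - 1), p$n_position_bins)
  lik[5] <- p$p_obs_correct
  expect_equal(belief_correct(prior, 5, p), lik * prior / sum(lik * prior))
  expect_error(belief_correct(prior, 0, p), "bin")
  # degenerate prior contradicting a noise-free observation resets to the
  # likelihood (with p_obs_correct < 1 the likelihood is everywhere
  # positive and the normalizer cannot vanish)
  p_exact <- list(n_position_bins = 2L, p_obs_correct = 1)
  expect_warning(post2 <- belief_correct(c(1, 0), 2, p_exact), "degenerate")
  expect_equal(post2, c(0, 1))
})

test_that("belief_summary reports argmax and entropy in nats", {
  expect_equal(belief_summary(rep(0.1, 10))$entropy, log(10))
  expect_equal(belief_summary(c(0, 1, 0))$entropy, 0)
  expect_identical(belief_summary(c(0.2, 0.5, 0.3))$map_position, 2L)
  s <- belief_summary(uniform_belief(driving_params()))
  expect_equal(s$entropy, log(21))
})

test_that("beliefs emitted by predict/correct stay valid distributions", {
  p <- driving_params()
  tau <- get_tau()
  set.seed(11)
  b <- point_belief(11, p)
  for (i in 1:50) {
    a <- sample.int(length(p$action_set), 1)
    b <- belief_predict(b, a, tau)
    expect_true(all(b >= 0))
    expect_equal(sum(b), 1, tolerance = 1e-9)
    if (i %% 5 == 0) {
      b <- belief_correct(b, sample.int(p$n_position_bins, 1), p)
      expect_true(all(b >= 0))
      expect_equal(sum(b), 1, tolerance = 1e-9)
    }
  }
})

test_that("entropy is non-decreasing under blind prediction with diffusive tau", {
  p <- driving_params()
  nb <- p$n_position_bins
  # strictly diffusive symmetric kernel on every action
  kern <- function(i) {
    row <- numeric(nb)
    row[i] <- 0.8
    if (i > 1) row[i - 1] <- row[i - 1] + 0.1 else row[i] <- row[i] + 0.1
    if (i < nb) row[i + 1] <- row[i + 1] + 0.1 else row[i] <- row[i] + 0.1
    row
  }
  M <- t(vapply(seq_len(nb), kern, numeric(nb)))
  na <- length(p$action_set)
  df <- tibble::tibble(
    from_bin = rep(rep(seq_len(nb), each = nb), times = na),
    action_index = rep(seq_len(na), each = nb * nb),
    to_bin = rep(rep(seq_len(nb), times = nb), times = na),
    probability = rep(as.vector(t(M)), times = na))
  tau_diff <- transition_model_from_df(df[df$probability > 0, ], p)
  b <- point_belief(11, p)
  prev <- belief_summary(b)$entropy
  for (i in 1:30) {
    b <- belief_predict(b, 3, tau_diff)
    ent <- belief_summary(b)$entropy
    expect_gte(ent, prev - 1e-12)
    prev <- ent
  }
})

test_that("fully observed training beats the random driving baseline", {
  p <- driving_params()
  tau <- get_tau()
  env <- make_driving_env(p, tau, observe = "always")
  set.seed(3)
  res <- train_policy(env, learning_params(n_episodes = 3000))
  set.seed(100)
  trained <- evaluate_driving_policy(p, tau, res$qtable, n_episodes = 100)
  set.seed(100)
  rand <- evaluate_driving_policy(p, tau, NULL, n_episodes = 100)
  expect_lt(mean(trained$mean_abs_offset), mean(rand$mean_abs_offset))
  expect_lt(sum(trained$n_out_of_bounds), sum(rand$n_out_of_bounds))
})

test_that("belief tracking matches the true bin on at least 90% of steps", {
  pol <- get_policies()
  set.seed(5)
  ev <- evaluate_driving_policy(pol$config$driving, pol$tau_d, pol$drive_q,
                                n_episodes = 50)
  expect_gte(mean(ev$map_match_rate), 0.9)
})

test_that("driving training log and reproducibility contracts hold", {
  p <- driving_params()
  tau <- get_tau()
  lp <- learning_params(n_episodes = 50)
  set.seed(9)
  r1 <- train_policy(make_driving_env(p, tau), lp)
  set.seed(9)
  r2 <- train_policy(make_driving_env(p, tau), lp)
  expect_identical(r1$qtable$q, r2$qtable$q)
  expect_identical(r1$log, r2$log)
  expect_named(r1$log, c("episode", "return", "steps", "tau"))
  expect_equal(nrow(r1$log), 50)
})
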