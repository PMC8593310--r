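# Shared training artifacts, built lazily once per test session.
# Training is by far the slowest part of the suite, so the full 2x2
# experiment (and the policy bundles it trains) is cached and reused by
# every test file that needs a trained model.

.cache <- new.env(parent = emptyenv())

# fast-profile 2x2 experiment: 4 conditions x 4 participants x 24 trials
get_experiment <- function() {
  if (is.null(.cache$exp)) {
    t0 <- Sys.time()
    .cache$exp <- run_experiment(n_participants = 4, n_trials = 24,
                                 profile = "fast", seed = 1)
    .cache$exp_minutes <- as.numeric(difftime(Sys.time(), t0, units = "mins"))
  }
  .cache$exp
}

get_experiment_minutes <- function() {
  get_experiment()
  .cache$exp_minutes
}

# trained policy bundle for the 60 km/h / 6 items condition
get_policies <- function() {
  if (!is.null(.cache$exp)) return(.cache$exp$policies$s60_i6)
  if (is.null(.cache$pol)) {
    .cache$pol <- train_policies(60, 6, profile = "fast", seed = 1)
  }
  .cache$pol
}

# a learned driving transition model (cheap relative to policy training)
get_tau <- function() {
  if (is.null(.cache$tau)) {
    p <- get_policies()
    .cache$tau <- p$tau_d
  }
  .cache$tau
}

# bootstrap percentile confidence interval for mean(x) - mean(y)
boot_diff_ci <- function(x, y, n_boot = 2000, conf = 0.95) {
  x <- x[is.finite(x)]
  y <- y[is.finite(y)]
  d <- vapply(seq_len(n_boot), function(i) {
    mean(sample(x, replace = TRUE)) - mean(sample(y, replace = TRUE))
  }, numeric(1))
  alpha <- (1 - conf) / 2
  unname(quantile(d, c(alpha, 1 - alpha)))
}
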