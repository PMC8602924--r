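# Independent oracles and shared fixtures. The oracles deliberately avoid the
# package's internal code paths: plain loops, direct density evaluation.

# Brute-force QUEST posterior: normalized prior x product of per-trial
# likelihoods over the same grid, computed with scalar loops and p_correct().
quest_posterior_oracle <- function(config, sizes, correct) {
  grid <- config$grid
  post <- dnorm(grid, log10(config$initial_guess_deg), config$guess_sd_log10)
  for (i in seq_along(sizes)) {
    for (g in seq_along(grid)) {
      p <- p_correct(sizes[i], 10^grid[g], config$psychometric)
      post[g] <- post[g] * if (correct[i]) p else (1 - p)
    }
  }
  post / sum(post)
}

# normalized posterior from a quest_state
quest_posterior <- function(state) {
  w <- exp(state$log_post - max(state$log_post))
  w / sum(w)
}

# Exhaustive shortest-window HDI: try every window of ceiling(mass * n)
# consecutive sorted points.
hdi_oracle <- function(x, mass) {
  x <- sort(x)
  n <- length(x)
  m <- ceiling(mass * n)
  if (m >= n) return(c(x[1], x[n]))
  best <- c(x[1], x[m])
  for (i in seq_len(n - m + 1)) {
    if (x[i + m - 1] - x[i] < best[2] - best[1]) best <- c(x[i], x[i + m - 1])
  }
  best
}

# Fast synthetic threshold table without running staircases: true thresholds
# plus small lognormal measurement noise, constant reported sd_log10.
quick_threshold_table <- function(n_participants = 6, seed = 1,
                                  noise_log10 = 0.02, config = NULL, ...) {
  config <- config %||% population_config(n_participants = n_participants, ...)
  truths <- sample_population(config, seed = seed)
  withr::with_seed(seed + 999, {
    truths$threshold_deg <- truths$true_threshold_deg *
      10^rnorm(nrow(truths), 0, noise_log10)
  })
  truths$sd_log10 <- noise_log10
  apply_exclusion(truths)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# One smoke-scale fit shared across test files (built lazily, once).
.fit_cache <- new.env(parent = emptyenv())
demo_fit <- function() {
  if (is.null(.fit_cache$fit)) {
    tb <- quick_threshold_table(n_participants = 8, seed = 42)
    .fit_cache$fit <- suppressWarnings(
      fit_ioa(tb, preset = "smoke", seed = 11)
    )
    .fit_cache$table <- tb
  }
  .fit_cache$fit
}
demo_table <- function() {
  demo_fit()
  .fit_cache$table
}
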