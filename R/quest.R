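#' QUEST staircase configuration
#'
#' The staircase maintains a gridded posterior over the log10 threshold. The
#' prior is Gaussian in log10 degrees, centred on the initial guess with the
#' given SD (both in log10 units, the staircase's native convention).
#' Defaults follow the reference experiment: initial guess 1.1 degrees, prior
#' SD 3 log10 units, Weibull psychometric parameters as in
#' [psychometric_params()], and stimulus placement clamped to 0.1--3 degrees.
#' The grid must span the prior: by default it covers the initial guess plus
#' or minus three prior SDs, in steps of 0.005 log10 units — far below the
#' 0.2 log10-unit exclusion cutoff. A grid clipped to the physical stimulus
#' range would truncate the deliberately diffuse prior and shift the
#' fresh-state estimate away from the initial guess.
#'
#' @param initial_guess_deg Prior mean threshold, degrees.
#' @param guess_sd_log10 Prior SD, log10 units.
#' @param grid_lo_log10,grid_hi_log10,grid_step_log10 Grid over log10
#'   threshold, degrees.
#' @param psychometric A [psychometric_params()].
#' @param size_min_deg,size_max_deg Placement clamp, degrees.
#' @return An object of class `quest_config`.
#' @examples
#' quest_config()
#' @export
quest_config <- function(initial_guess_deg = 1.1,
                         guess_sd_log10 = 3,
                         grid_lo_log10 = log10(initial_guess_deg) - 3 * guess_sd_log10,
                         grid_hi_log10 = log10(initial_guess_deg) + 3 * guess_sd_log10,
                         grid_step_log10 = 0.005,
                         psychometric = psychometric_params(),
                         size_min_deg = 0.1,
                         size_max_deg = 3.0) {
  if (grid_step_log10 <= 0) abort("grid_step_log10 must be positive")
  if (grid_lo_log10 >= grid_hi_log10) abort("grid bounds must be increasing")
  if (grid_lo_log10 > log10(initial_guess_deg) - 3 * guess_sd_log10 + 1e-9 ||
      grid_hi_log10 < log10(initial_guess_deg) + 3 * guess_sd_log10 - 1e-9) {
    abort("grid must span the prior: initial guess +/- 3 prior SDs in log10 space")
  }
  if (size_min_deg <= 0 || size_min_deg >= size_max_deg) {
    abort("need 0 < size_min_deg < size_max_deg")
  }
  structure(
    list(
      initial_guess_deg = initial_guess_deg,
      guess_sd_log10 = guess_sd_log10,
      grid = seq(grid_lo_log10, grid_hi_log10, by = grid_step_log10),
      grid_step_log10 = grid_step_log10,
      psychometric = psychometric,
      size_min_deg = size_min_deg,
      size_max_deg = size_max_deg
    ),
    class = "quest_config"
  )
}

#' Initialise a QUEST staircase
#'
#' @param config A [quest_config()].
#' @return An object of class `quest_state`: the config, the unnormalised log
#'   posterior over the grid (initially the Gaussian prior), and the trial
#'   history.
#' @examples
#' s <- quest_init()
#' quest_estimate(s) # prior mean ~ 1.1 deg, SD ~ 3 log10 units
#' @export
quest_init <- function(config = quest_config()) {
  structure(
    list(
      config = config,
      log_post = dnorm(config$grid, log10(config$initial_guess_deg),
                       config$guess_sd_log10, log = TRUE),
      sizes = numeric(0),
      correct = logical(0)
    ),
    class = "quest_state"
  )
}

#' @export
print.quest_state <- function(x, ...) {
  est <- quest_estimate(x)
  cat(sprintf("<quest_state> %d trials; threshold %.3g deg (posterior SD %.3g log10 units)\n",
              length(x$sizes), est$threshold_deg, est$sd_log10))
  invisible(x)
}

# normalised posterior weights over the grid
posterior_weights <- function(state) {
  w <- exp(state$log_post - max(state$log_post))
  w / sum(w)
}

#' Update the staircase posterior with one trial
#'
#' Adds the trial's log likelihood, \eqn{\log \Psi} for a correct response or
#' \eqn{\log(1-\Psi)} for an error, evaluated across the threshold grid. The
#' posterior after a set of trials does not depend on their order.
#'
#' @param state A `quest_state`.
#' @param size_deg Size actually shown, degrees; must lie within the
#'   placement bounds.
#' @param correct Logical response.
#' @return The updated `quest_state`.
#' @export
quest_update <- function(state, size_deg, correct) {
  cfg <- state$config
  if (size_deg < cfg$size_min_deg || size_deg > cfg$size_max_deg) {
    abort(sprintf("size %.4g deg outside [%g, %g]", size_deg,
                  cfg$size_min_deg, cfg$size_max_deg))
  }
  p <- psi_logdiff(log10(size_deg) - cfg$grid, cfg$psychometric)
  state$log_post <- state$log_post + if (isTRUE(correct)) log(p) else log1p(-p)
  state$sizes <- c(state$sizes, size_deg)
  state$correct <- c(state$correct, isTRUE(correct))
  state
}

#' Recommended size for the next trial
#'
#' Mean of the posterior over log10 threshold, exponentiated and clamped to
#' the placement bounds (mean placement, the standard recommendation for this
#' staircase family).
#'
#' @param state A `quest_state`.
#' @return Size in degrees.
#' @export
recommend_size <- function(state) {
  w <- posterior_weights(state)
  min(max(10^sum(w * state$config$grid), state$config$size_min_deg),
      state$config$size_max_deg)
}

#' Threshold estimate and posterior SD
#'
#' @param state A `quest_state`.
#' @return A one-row tibble: `threshold_deg` (10 to the posterior mean of
#'   log10 threshold), `sd_log10` (posterior SD of log10 threshold, the
#'   quantity the reliability exclusion tests), `n_trials`.
#' @export
quest_estimate <- function(state) {
  w <- posterior_weights(state)
  m <- sum(w * state$config$grid)
  v <- sum(w * (state$config$grid - m)^2)
  tibble::tibble(
    threshold_deg = 10^m,
    sd_log10 = sqrt(v),
    n_trials = length(state$sizes)
  )
}

# one adaptive run of n trials against a simulated observer
quest_run <- function(true_threshold_deg, n_trials, config) {
  state <- quest_init(config)
  sizes <- numeric(n_trials)
  correct <- logical(n_trials)
  for (i in seq_len(n_trials)) {
    s <- recommend_size(state)
    r <- simulate_trial(s, true_threshold_deg, config$psychometric)
    state <- quest_update(state, s, r)
    sizes[i] <- s
    correct[i] <- r
  }
  list(state = state, sizes = sizes, correct = correct)
}

#' Measure one condition cell: two runs plus pooled re-evaluation
#'
#' Runs the staircase twice from a fresh prior, each run adapting over
#' `trials_per_run` trials, then re-evaluates the pooled trials: a third
#' QUEST pass over all `2 x trials_per_run` (size, correct) pairs starting
#' again from the fresh prior, with no adaptation. The pooled pass's estimate
#' and posterior SD are the cell's threshold; because likelihood products
#' commute it is invariant to the order of the pooled trials.
#'
#' @param true_threshold_deg Simulated observer's true threshold, degrees.
#' @param design A [study_design()] (supplies runs per cell and trials per
#'   run).
#' @param config A [quest_config()].
#' @return A list with `estimate` (one-row tibble `threshold_deg, sd_log10,
#'   n_trials`) and `trials` (tibble `run, trial, size_deg, correct`).
#' @examples
#' withr::with_seed(1, run_cell(0.5)$estimate)
#' @export
run_cell <- function(true_threshold_deg, design = study_design(),
                     config = quest_config()) {
  runs <- lapply(seq_len(design$runs_per_cell), function(r) {
    quest_run(true_threshold_deg, design$trials_per_run, config)
  })
  pooled <- quest_init(config)
  for (r in runs) {
    for (i in seq_along(r$sizes)) {
      pooled <- quest_update(pooled, r$sizes[i], r$correct[i])
    }
  }
  trials <- tibble::tibble(
    run = rep(seq_along(runs), each = design$trials_per_run),
    trial = rep(seq_len(design$trials_per_run), times = length(runs)),
    size_deg = unlist(lapply(runs, `[[`, "sizes")),
    correct = unlist(lapply(runs, `[[`, "correct"))
  )
  list(estimate = quest_estimate(pooled), trials = trials)
}

#' Simulate staircase threshold estimation for a whole cohort
#'
#' For every observer and condition cell in `truths`, runs [run_cell()] and
#' collects the pooled estimates into the pipeline's central threshold table.
#'
#' @param truths Ground-truth tibble from [sample_population()] (columns
#'   `participant, design, location, flanker, true_threshold_deg`).
#' @param design A [study_design()].
#' @param config A [quest_config()].
#' @param seed Integer seed for the whole simulation.
#' @param keep_trials If `TRUE`, attach the trial-level records as attribute
#'   `"trials"` (a tibble with the same keys plus `run, trial, size_deg,
#'   correct`).
#' @return A tibble with one row per (participant, cell): `participant,
#'   design, location, flanker, cell, true_threshold_deg, threshold_deg,
#'   sd_log10, n_trials`.
#' @examples
#' truths <- sample_population(population_config(n_participants = 1), seed = 1)
#' th <- simulate_cohort(truths[1:3, ], seed = 1)
#' @export
simulate_cohort <- function(truths, design = study_design(),
                            config = quest_config(), seed = 1L,
                            keep_trials = FALSE) {
  withr::local_seed(as.integer(seed))
  res <- vector("list", nrow(truths))
  for (i in seq_len(nrow(truths))) {
    res[[i]] <- run_cell(truths$true_threshold_deg[i], design, config)
  }
  est <- dplyr::bind_rows(lapply(res, `[[`, "estimate"))
  out <- dplyr::bind_cols(
    truths[, intersect(c("participant", "design", "location", "flanker",
                         "cell", "true_threshold_deg"), names(truths))],
    est
  )
  if (keep_trials) {
    keys <- truths[rep(seq_len(nrow(truths)),
                       each = design$runs_per_cell * design$trials_per_run),
                   intersect(c("participant", "design", "location", "flanker"),
                             names(truths))]
    attr(out, "trials") <- dplyr::bind_cols(
      keys, dplyr::bind_rows(lapply(res, `[[`, "trials"))
    )
  }
  out
}
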