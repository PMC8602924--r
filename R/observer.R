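#' Psychometric function parameters
#'
#' Parameters of the Weibull psychometric function used both to simulate
#' observers and inside the QUEST staircase:
#' \deqn{\Psi(x) = \delta\gamma + (1-\delta)\,[1 - (1-\gamma)
#'   \exp(-10^{\,\beta (x - t) + \epsilon})]}
#' with \eqn{x} and \eqn{t} the letter size and threshold in log10 degrees,
#' \eqn{\gamma} the guess rate, \eqn{\delta} the lapse rate and \eqn{\beta}
#' the slope. Lapses succeed at chance (the \eqn{\delta\gamma} term). The
#' offset \eqn{\epsilon} is solved so that \eqn{\Psi(t)} equals the threshold
#' criterion exactly; performance therefore depends on size and threshold
#' only through their log-ratio.
#'
#' Defaults are the staircase settings of the reference experiment: guess
#' rate 1/9 (9AFC letter identification; commonly quoted as 0.11), slope 3.5,
#' lapse rate 0.05, threshold criterion 0.5.
#'
#' @param guess_rate Probability correct by guessing (lower asymptote).
#' @param slope_beta Weibull slope in log10 units.
#' @param lapse_rate Probability of a stimulus-independent lapse; the upper
#'   asymptote is `1 - lapse_rate * (1 - guess_rate)`.
#' @param threshold_criterion Proportion correct defining the threshold.
#' @return An object of class `psychometric_params` with the inputs plus the
#'   solved `offset_epsilon` (log10 units).
#' @examples
#' pp <- psychometric_params()
#' p_correct(0.5, 0.5, pp) # == threshold criterion, 0.5
#' @export
psychometric_params <- function(guess_rate = 1 / 9,
                                slope_beta = 3.5,
                                lapse_rate = 0.05,
                                threshold_criterion = 0.5) {
  upper <- 1 - lapse_rate * (1 - guess_rate)
  if (!(guess_rate > 0 && guess_rate < threshold_criterion &&
        threshold_criterion < upper)) {
    abort("need 0 < guess_rate < threshold_criterion < 1 - lapse_rate * (1 - guess_rate)")
  }
  if (slope_beta <= 0) abort("slope_beta must be positive")
  # Psi(t) = criterion  <=>  exp(-10^eps) = (1 - (crit - lapse*guess)/(1-lapse)) / (1-guess)
  inner <- (1 - (threshold_criterion - lapse_rate * guess_rate) / (1 - lapse_rate)) /
    (1 - guess_rate)
  structure(
    list(
      guess_rate = guess_rate,
      slope_beta = slope_beta,
      lapse_rate = lapse_rate,
      threshold_criterion = threshold_criterion,
      offset_epsilon = log10(-log(inner))
    ),
    class = "psychometric_params"
  )
}

#' @export
print.psychometric_params <- function(x, ...) {
  cat(sprintf(
    "<psychometric_params> guess %.4g, slope %.3g, lapse %.3g, criterion %.3g (epsilon %.6g)\n",
    x$guess_rate, x$slope_beta, x$lapse_rate, x$threshold_criterion,
    x$offset_epsilon
  ))
  invisible(x)
}

# core evaluation on the log10 size - log10 threshold difference; vectorised
psi_logdiff <- function(d_log10, params) {
  params$lapse_rate * params$guess_rate +
    (1 - params$lapse_rate) *
      (1 - (1 - params$guess_rate) *
         exp(-10^(params$slope_beta * d_log10 + params$offset_epsilon)))
}

#' Probability of a correct response
#'
#' Evaluates the Weibull psychometric function for a letter of size
#' `size_deg` shown to an observer whose true threshold is
#' `true_threshold_deg`. Strictly increasing in size, strictly decreasing in
#' threshold, equal to the threshold criterion when the two coincide.
#'
#' @param size_deg Letter size(s), degrees; positive.
#' @param true_threshold_deg True threshold(s), degrees; positive.
#' @param params A [psychometric_params()].
#' @return Probability (vectorised over inputs).
#' @examples
#' p_correct(c(0.1, 0.5, 5), 0.5, psychometric_params())
#' @export
p_correct <- function(size_deg, true_threshold_deg,
                      params = psychometric_params()) {
  if (any(size_deg <= 0) || any(true_threshold_deg <= 0)) {
    abort("size_deg and true_threshold_deg must be positive")
  }
  psi_logdiff(log10(size_deg) - log10(true_threshold_deg), params)
}

#' Population ground-truth configuration
#'
#' Describes the synthetic cohort in the same multiplicative terms as the
#' analysis model reports: a median unflanked threshold per location, an
#' inward crowding factor and an in-out asymmetry ratio per design x
#' location, and between-observer standard deviations (log10 units) for
#' observer-level offsets mirroring the model's random-effect structure
#' (intercept, three location dummies, two flanker dummies, two design
#' dummies). The implied outward threshold is
#' `unflanked * cf_inward * ioa`.
#'
#' Defaults emulate the reference experiment: unflanked thresholds around
#' 0.6 degrees at 7.5 degrees eccentricity, inward crowding factor 2 and IOA
#' 2.5 in every cell (squarely inside the 1.5--4.5 range reported for human
#' observers), 0.1 log10 units of between-observer spread on overall acuity
#' and 0.05 on each condition effect.
#'
#' @param n_participants Cohort size.
#' @param unflanked_median_deg Median unflanked threshold; scalar or named
#'   vector over locations (`up, down, left, right`).
#' @param true_cf_inward Inward crowding factor (>= 1); scalar, or a data
#'   frame with columns `design, location, cf_inward` covering all 12 pairs.
#' @param true_ioa In-out asymmetry ratio (> 0); scalar, or a data frame with
#'   columns `design, location, ioa` covering all 12 pairs.
#' @param sd_intercept,sd_location,sd_flanker,sd_design Between-observer SDs
#'   in log10 units for the observer offsets.
#' @param psychometric A [psychometric_params()] shared by all observers.
#' @return An object of class `population_config`.
#' @examples
#' population_config(n_participants = 12, true_ioa = 1)
#' @export
population_config <- function(n_participants = 38,
                              unflanked_median_deg = 0.6,
                              true_cf_inward = 2.0,
                              true_ioa = 2.5,
                              sd_intercept = 0.1,
                              sd_location = 0.05,
                              sd_flanker = 0.05,
                              sd_design = 0.05,
                              psychometric = psychometric_params()) {
  unfl <- expand_by_location(unflanked_median_deg, "unflanked_median_deg")
  cf <- expand_by_cell(true_cf_inward, "cf_inward")
  ioa <- expand_by_cell(true_ioa, "ioa")
  if (any(unfl <= 0)) abort("unflanked_median_deg must be positive")
  if (any(cf$cf_inward < 1)) abort("true_cf_inward must be >= 1")
  if (any(ioa$ioa <= 0)) abort("true_ioa must be positive")
  sds <- c(sd_intercept, sd_location, sd_flanker, sd_design)
  if (any(sds < 0)) abort("between-observer SDs must be nonnegative")
  structure(
    list(
      n_participants = as.integer(n_participants),
      unflanked_median_deg = unfl,
      true_cf_inward = cf,
      true_ioa = ioa,
      sd_intercept = sd_intercept,
      sd_location = sd_location,
      sd_flanker = sd_flanker,
      sd_design = sd_design,
      psychometric = psychometric
    ),
    class = "population_config"
  )
}

expand_by_location <- function(x, what) {
  if (is.numeric(x) && length(x) == 1) {
    return(setNames(rep(x, 4), location_levels))
  }
  if (is.numeric(x) && !is.null(names(x)) && setequal(names(x), location_levels)) {
    return(x[location_levels])
  }
  abort(sprintf("%s must be a scalar or a named vector over the four locations", what))
}

expand_by_cell <- function(x, col) {
  pairs <- unique(condition_cells()[, c("design", "location")])
  if (is.numeric(x) && length(x) == 1) {
    pairs[[col]] <- x
    return(pairs)
  }
  if (is.data.frame(x) && all(c("design", "location", col) %in% names(x))) {
    out <- dplyr::left_join(
      pairs,
      dplyr::mutate(x,
        design = as_design(.data$design),
        location = as_location(.data$location)
      ),
      by = c("design", "location")
    )
    if (anyNA(out[[col]])) abort(sprintf("%s table must cover all 12 design x location pairs", col))
    return(out)
  }
  abort(sprintf("%s must be a scalar or a data frame with design, location, %s", col, col))
}

#' Ground-truth population IOA per design x location
#'
#' @param config A [population_config()].
#' @return Tibble with columns `design, location, ioa`.
#' @export
true_ioa_table <- function(config) {
  tibble::as_tibble(config$true_ioa)
}

#' Sample a cohort of synthetic observers
#'
#' Draws one ground-truth threshold per observer per condition cell. On the
#' log10 scale each truth is the population cell value (unflanked median,
#' times the inward crowding factor for inward cells, times crowding factor
#' x IOA for outward cells) plus the observer's offsets: an intercept offset
#' and, where the cell activates them, location/flanker/design dummy offsets,
#' each drawn from a centred normal with the configured SD. With all SDs zero
#' every observer equals the population truth.
#'
#' @param config A [population_config()].
#' @param seed Integer seed.
#' @return A tibble with `n_participants * 36` rows: `participant, design,
#'   location, flanker, cell, true_threshold_deg`. The observer offset matrix
#'   is attached as attribute `"offsets"` for inspection.
#' @examples
#' truths <- sample_population(population_config(n_participants = 2), seed = 1)
#' nrow(truths) # 72
#' @export
sample_population <- function(config = population_config(), seed = 1L) {
  withr::local_seed(as.integer(seed))
  cells <- condition_cells()
  n <- config$n_participants

  # population log10 threshold per cell
  base <- unname(log10(config$unflanked_median_deg[as.character(cells$location)]))
  cf <- dplyr::left_join(cells, config$true_cf_inward, by = c("design", "location"))$cf_inward
  ioa <- dplyr::left_join(cells, config$true_ioa, by = c("design", "location"))$ioa
  pop_log10 <- base +
    ifelse(cells$flanker == "inward", log10(cf), 0) +
    ifelse(cells$flanker == "outward", log10(cf * ioa), 0)

  offset_names <- c("intercept", paste0("loc_", location_levels[-1]),
                    paste0("fl_", c("inward", "outward")),
                    paste0("des_", c("precued", "random")))
  offset_sds <- c(config$sd_intercept, rep(config$sd_location, 3),
                  rep(config$sd_flanker, 2), rep(config$sd_design, 2))
  offsets <- matrix(rnorm(n * length(offset_sds), 0, rep(offset_sds, each = n)),
                    nrow = n, dimnames = list(NULL, offset_names))

  # observer dummy activation per cell (reference: up / none / blocked)
  Zc <- cbind(
    intercept = rep(1, nrow(cells)),
    loc_down = as.numeric(cells$location == "down"),
    loc_left = as.numeric(cells$location == "left"),
    loc_right = as.numeric(cells$location == "right"),
    fl_inward = as.numeric(cells$flanker == "inward"),
    fl_outward = as.numeric(cells$flanker == "outward"),
    des_precued = as.numeric(cells$design == "precued"),
    des_random = as.numeric(cells$design == "random")
  )

  out <- tidyr::expand_grid(participant = seq_len(n), cells)
  shift <- as.vector(Zc %*% t(offsets))  # participant-major, cells in canonical order
  out$true_threshold_deg <- 10^(rep(pop_log10, times = n) + shift)
  if (any(!is.finite(out$true_threshold_deg) | out$true_threshold_deg <= 0)) {
    abort("generated true thresholds must be positive and finite")
  }
  attr(out, "offsets") <- offsets
  out
}

#' Simulate one 9AFC trial
#'
#' Bernoulli draw from the psychometric function: correct with probability
#' [p_correct()] for the given size and true threshold.
#'
#' @param size_deg Presented letter size, degrees.
#' @param true_threshold_deg Observer's true threshold for the cell, degrees.
#' @param params A [psychometric_params()].
#' @return Logical scalar (vectorised over sizes).
#' @examples
#' withr::with_seed(1, simulate_trial(2, 0.5))
#' @export
simulate_trial <- function(size_deg, true_threshold_deg,
                           params = psychometric_params()) {
  p <- p_correct(size_deg, true_threshold_deg, params)
  runif(length(p)) < p
}
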