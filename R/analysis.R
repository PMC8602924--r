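#' Highest-density interval of a sample
#'
#' The shortest contiguous interval of the sorted sample containing
#' `ceiling(mass * n)` points. For unimodal posteriors this is the HPDI; ties
#' between equally short windows are broken toward the lowest window.
#'
#' @param samples Numeric vector (at least 2 values unless all identical).
#' @param mass Probability mass in (0, 1).
#' @return Named numeric vector `c(lower, upper)`.
#' @examples
#' hdi(c(1, 2, 3, 4, 5), 0.6) # c(1, 3)
#' @export
hdi <- function(samples, mass = 0.97) {
  if (length(samples) == 0) abort("empty sample")
  if (!(mass > 0 && mass < 1)) abort("mass must be in (0, 1)")
  x <- sort(samples)
  n <- length(x)
  m <- ceiling(mass * n)
  if (m >= n) return(c(lower = x[1], upper = x[n]))
  widths <- x[m:n] - x[1:(n - m + 1)]
  i <- which.min(widths)
  c(lower = x[i], upper = x[i + m - 1])
}

#' Exceedance probability
#'
#' Fraction of draws strictly greater than the criterion.
#'
#' @param samples Numeric vector of draws.
#' @param criterion Threshold value.
#' @return Probability in \[0, 1\].
#' @examples
#' exceedance(c(1, 2, 3), 1.5)
#' @export
exceedance <- function(samples, criterion) {
  if (length(samples) == 0) abort("empty sample")
  mean(samples > criterion)
}

# X row for one cell
cell_row <- function(design, location, flanker) {
  fixed_design_matrix(tibble::tibble(
    design = design, location = location, flanker = flanker
  ))$X
}

#' Posterior threshold draws for one condition cell
#'
#' The model's prediction for the average observer: fixed effects only,
#' random effects at zero. Per draw, the exponentiated sum of the cell's
#' active coefficients.
#'
#' @param fit An `ioa_fit`.
#' @param design,location,flanker Cell coordinates.
#' @return Numeric vector of thresholds (degrees), one per draw.
#' @export
cell_threshold_draws <- function(fit, design, location, flanker) {
  as.numeric(exp(fit$draws$beta %*% t(cell_row(design, location, flanker))))
}

#' Posterior crowding-factor draws
#'
#' Ratio of the flanked to the matching unflanked threshold, per draw. A
#' value above 1 indicates crowding.
#'
#' @param fit An `ioa_fit`.
#' @param design,location Cell coordinates.
#' @param flanker `"inward"` or `"outward"` (the unflanked cell is the
#'   denominator, so `"none"` is an error).
#' @return Numeric vector of ratios, one per draw.
#' @export
crowding_factor_draws <- function(fit, design, location, flanker) {
  flanker <- as.character(flanker)
  if (!flanker %in% c("inward", "outward")) {
    abort('flanker must be "inward" or "outward"')
  }
  d <- cell_row(design, location, flanker) - cell_row(design, location, "none")
  as.numeric(exp(fit$draws$beta %*% t(d)))
}

#' Posterior in-out asymmetry draws
#'
#' Ratio of the outward-flanked to the inward-flanked threshold per draw —
#' identically the ratio of the two crowding factors, since the unflanked
#' threshold cancels.
#'
#' @param fit An `ioa_fit`.
#' @param design,location Cell coordinates.
#' @return Numeric vector of IOA ratios, one per draw.
#' @export
ioa_draws <- function(fit, design, location) {
  d <- cell_row(design, location, "outward") - cell_row(design, location, "inward")
  as.numeric(exp(fit$draws$beta %*% t(d)))
}

#' Summary table of the in-out asymmetry
#'
#' Per design x location: the posterior median IOA ratio, HPDIs at the
#' requested masses, and exceedance probabilities at the requested criteria.
#'
#' @param fit An `ioa_fit`.
#' @param masses HPDI masses (default the reporting convention 53% and 97%).
#' @param criteria Exceedance criteria (default 1 — any asymmetry — and 1.5,
#'   a conservative asymmetry).
#' @return A tibble with one row per (design, location): `design, location,
#'   median`, `hdi<mass>_lo/_hi` per mass, `p_gt_<criterion>` per criterion.
#' @examples
#' \donttest{
#' # ioa_table(fit) |> dplyr::arrange(location, design)
#' }
#' @export
ioa_table <- function(fit, masses = c(0.53, 0.97), criteria = c(1, 1.5)) {
  pairs <- unique(condition_cells()[, c("design", "location")])
  purrr::pmap_dfr(pairs, function(design, location) {
    draws <- ioa_draws(fit, design, location)
    row <- tibble::tibble(design = design, location = location,
                          median = median(draws))
    for (m in masses) {
      ci <- hdi(draws, m)
      row[[sprintf("hdi%d_lo", round(100 * m))]] <- ci[["lower"]]
      row[[sprintf("hdi%d_hi", round(100 * m))]] <- ci[["upper"]]
    }
    for (cr in criteria) {
      row[[paste0("p_gt_", sub("\\.", "_", format(cr)))]] <- exceedance(draws, cr)
    }
    row
  })
}

#' Summary table of crowding factors
#'
#' Posterior median and HPDI of the crowding factor for each design x
#' location x flanker (inward, outward) combination, with the probability
#' that crowding is present (factor > 1).
#'
#' @param fit An `ioa_fit`.
#' @param mass HPDI mass.
#' @return A tibble with 24 rows: `design, location, flanker, median,
#'   hdi_lo, hdi_hi, p_gt_1`.
#' @export
crowding_table <- function(fit, mass = 0.97) {
  grid <- unique(condition_cells()[, c("design", "location")])
  grid <- tidyr::expand_grid(grid, flanker = c("inward", "outward"))
  purrr::pmap_dfr(grid, function(design, location, flanker) {
    draws <- crowding_factor_draws(fit, design, location, flanker)
    ci <- hdi(draws, mass)
    tibble::tibble(design = design, location = location, flanker = flanker,
                   median = median(draws), hdi_lo = ci[["lower"]],
                   hdi_hi = ci[["upper"]], p_gt_1 = exceedance(draws, 1))
  })
}

pool_ioa_draws <- function(fit, cells, pool = c("geometric", "arithmetic")) {
  pool <- match.arg(pool)
  mat <- sapply(seq_len(nrow(cells)), function(i) {
    ioa_draws(fit, cells$design[i], cells$location[i])
  })
  if (is.null(dim(mat))) mat <- matrix(mat, ncol = 1)
  if (pool == "geometric") exp(rowMeans(log(mat))) else rowMeans(mat)
}

#' Ratio of IOA between two (pools of) cells
#'
#' Per draw, the IOA of the numerator cell — or the pooled IOA over several
#' cells — divided by that of the denominator. Ratios are multiplicative, so
#' pooling defaults to the geometric mean of the per-draw IOA values
#' (switchable to arithmetic). Used for the visual-field contrasts (up vs
#' down, horizontal vs vertical meridian) and the design contrasts.
#'
#' @param fit An `ioa_fit`.
#' @param numerator,denominator Data frames with columns `design, location`
#'   (one or more rows each); they must not overlap.
#' @param pool `"geometric"` (default) or `"arithmetic"`.
#' @return A list: `draws` (per-draw ratio), `median`, `hdi97`, `p_gt_1`.
#' @examples
#' \donttest{
#' # horizontal vs vertical meridian within the blocked design:
#' # contrast_ratio(fit,
#' #   numerator  = data.frame(design = "blocked", location = c("left", "right")),
#' #   denominator = data.frame(design = "blocked", location = c("up", "down")))
#' }
#' @export
contrast_ratio <- function(fit, numerator, denominator,
                           pool = c("geometric", "arithmetic")) {
  numerator <- tibble::as_tibble(numerator)
  denominator <- tibble::as_tibble(denominator)
  overlap <- dplyr::inner_join(
    dplyr::mutate_all(numerator[, c("design", "location")], as.character),
    dplyr::mutate_all(denominator[, c("design", "location")], as.character),
    by = c("design", "location")
  )
  if (nrow(overlap) > 0) abort("numerator and denominator pools overlap")
  ratio <- pool_ioa_draws(fit, numerator, pool) /
    pool_ioa_draws(fit, denominator, pool)
  list(draws = ratio, median = median(ratio), hdi97 = hdi(ratio, 0.97),
       p_gt_1 = exceedance(ratio, 1))
}

#' Simulate a population of new observers from the fitted model
#'
#' Individual-differences analysis: each simulated participant takes one
#' posterior draw (propagating posterior uncertainty) and draws observer
#' offsets for the intercept and each main-effect dummy from that draw's
#' random-effect SDs. The participant's IOA in a cell is then
#' `exp(fixed-effect IOA contrast + outward offset - inward offset)`.
#' Reported per design x location: the proportion of simulated participants
#' whose IOA exceeds each criterion, and the median and spread of the
#' simulated IOA.
#'
#' @param fit An `ioa_fit`.
#' @param n_participants Number of simulated participants (default 1000).
#' @param criteria IOA criteria for the reported proportions.
#' @param seed Integer seed.
#' @return An object of class `ioa_population`: `participants` (tibble,
#'   one row per simulated participant x design x location with its `ioa`)
#'   and `summary` (per design x location: `median, sd_log10, prop_gt_*`).
#' @export
simulate_population <- function(fit, n_participants = 1000,
                                criteria = c(1, 1.5), seed = 1L) {
  withr::local_seed(as.integer(seed))
  D <- n_draws(fit)
  idx <- sample.int(D, n_participants, replace = TRUE)
  sd_in <- fit$draws$sd_b[idx, "fl_inward"]
  sd_out <- fit$draws$sd_b[idx, "fl_outward"]
  off_in <- rnorm(n_participants, 0, sd_in)
  off_out <- rnorm(n_participants, 0, sd_out)

  pairs <- unique(condition_cells()[, c("design", "location")])
  participants <- purrr::pmap_dfr(pairs, function(design, location) {
    fixed <- ioa_draws(fit, design, location)[idx]
    tibble::tibble(
      sim_participant = seq_len(n_participants),
      design = design, location = location,
      ioa = fixed * exp(off_out - off_in)
    )
  })
  summary <- participants |>
    dplyr::group_by(.data$design, .data$location) |>
    dplyr::summarise(
      median = median(.data$ioa),
      sd_log10 = sd(log10(.data$ioa)),
      .groups = "drop"
    )
  for (cr in criteria) {
    props <- participants |>
      dplyr::group_by(.data$design, .data$location) |>
      dplyr::summarise(p = mean(.data$ioa > cr), .groups = "drop")
    summary[[paste0("prop_gt_", sub("\\.", "_", format(cr)))]] <- props$p
  }
  structure(
    list(participants = participants, summary = summary,
         n_participants = n_participants, criteria = criteria,
         seed = as.integer(seed)),
    class = "ioa_population"
  )
}

#' @export
print.ioa_population <- function(x, ...) {
  cat(sprintf("<ioa_population> %d simulated participants x %d cells\n",
              x$n_participants, nrow(x$summary)))
  print(x$summary)
  invisible(x)
}
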