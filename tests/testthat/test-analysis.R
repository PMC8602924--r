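test_that("hdi matches the exhaustive shortest-window oracle", {
  expect_equal(unname(hdi(c(1, 2, 3, 4, 5), 0.6)), c(1, 3))
  withr::with_seed(12, {
    for (rep in 1:40) {
      n <- sample(5:2000, 1)
      x <- switch(sample(3, 1),
                  rnorm(n),
                  rlnorm(n, 0, 0.5),
                  c(rnorm(n %/% 2), rnorm(n - n %/% 2, 6)))
      for (mass in c(0.53, 0.75, 0.97)) {
        expect_equal(unname(hdi(x, mass)), hdi_oracle(x, mass))
      }
    }
  })
  # symmetric unimodal: matches central quantile interval to MC error
  withr::with_seed(2, x <- rnorm(2e5))
  expect_equal(unname(hdi(x, 0.97)), qnorm(c(0.015, 0.985)), tolerance = 0.05)
  # degenerate sample
  expect_equal(unname(hdi(rep(2, 10), 0.5)), c(2, 2))
  expect_error(hdi(numeric(0), 0.5), "empty")
  expect_error(hdi(1:5, 1.2), "mass")
})

test_that("exceedance is the strict fraction above the criterion", {
  expect_equal(exceedance(rep(2, 5), 1.5), 1)
  expect_equal(exceedance(rep(1, 5), 1), 0)
  withr::with_seed(3, x <- rnorm(1e5, 2, 1))
  expect_equal(exceedance(x, 2), 0.5, tolerance = 0.01)
  # monotone nonincreasing in the criterion
  ps <- sapply(c(0, 1, 1.5, 2, 3), function(k) exceedance(x, k))
  expect_true(all(diff(ps) <= 0))
})

test_that("cell predictions are the exponentiated sums of active coefficients", {
  fit <- demo_fit()
  # synthetic single-draw check against a naive per-cell evaluator
  fake <- fit
  fake$draws$beta <- matrix(0, 1, 36, dimnames = list(NULL, colnames(fit$draws$beta)))
  expect_equal(cell_threshold_draws(fake, "blocked", "up", "none"), 1)
  fake$draws$beta[1, "loc_up"] <- 1
  expect_equal(cell_threshold_draws(fake, "blocked", "up", "none"), exp(1))
  # naive evaluator on the real fit, every cell, first 50 draws
  cells <- condition_cells()
  X <- crowdasym:::fixed_design_matrix(cells)$X
  for (i in seq_len(nrow(cells))) {
    naive <- exp(rowSums(sweep(fit$draws$beta[1:50, X[i, ] == 1, drop = FALSE],
                               2, 1, "*")))
    expect_equal(
      cell_threshold_draws(fit, cells$design[i], cells$location[i],
                           cells$flanker[i])[1:50],
      naive, tolerance = 1e-12
    )
  }
  expect_error(cell_threshold_draws(fit, "blocked", "middle", "none"),
               "unknown location")
})

test_that("IOA equals the crowding-factor ratio draw by draw", {
  fit <- demo_fit()
  for (loc in c("up", "left")) {
    cf_in <- crowding_factor_draws(fit, "random", loc, "inward")
    cf_out <- crowding_factor_draws(fit, "random", loc, "outward")
    expect_equal(ioa_draws(fit, "random", loc), cf_out / cf_in,
                 tolerance = 1e-12)
  }
  expect_error(crowding_factor_draws(fit, "blocked", "up", "none"),
               "inward")
})

test_that("ratio statistics are invariant to a common threshold rescaling", {
  fit <- demo_fit()
  scaled <- fit
  # multiplying every threshold by a constant adds log(k) to all four
  # location intercepts and leaves every ratio unchanged
  scaled$draws$beta[, 1:4] <- scaled$draws$beta[, 1:4] + log(7)
  expect_equal(ioa_draws(scaled, "precued", "down"),
               ioa_draws(fit, "precued", "down"), tolerance = 1e-12)
  expect_equal(crowding_factor_draws(scaled, "blocked", "left", "outward"),
               crowding_factor_draws(fit, "blocked", "left", "outward"),
               tolerance = 1e-12)
})

test_that("the IOA table recovers the generating asymmetry in every cell", {
  tab <- ioa_table(demo_fit())
  expect_equal(nrow(tab), 12)
  expect_named(tab, c("design", "location", "median", "hdi53_lo", "hdi53_hi",
                      "hdi97_lo", "hdi97_hi", "p_gt_1", "p_gt_1_5"))
  # 53% HPDI nested in the 97% HPDI
  expect_true(all(tab$hdi97_lo <= tab$hdi53_lo & tab$hdi53_hi <= tab$hdi97_hi))
  # demo generator has IOA 2.5 everywhere
  expect_true(all(tab$hdi97_lo <= 2.5 * 1.15 & tab$hdi97_hi >= 2.5 * 0.85))
  expect_true(all(tab$p_gt_1 > 0.99))
})

test_that("crowding factors exceed one wherever the generator crowds", {
  tab <- crowding_table(demo_fit())
  expect_equal(nrow(tab), 24)
  expect_true(all(tab$p_gt_1 > 0.95))
  expect_true(all(tab$median > 1))
})

test_that("contrast ratios detect equality and reject overlapping pools", {
  fit <- demo_fit()
  same <- contrast_ratio(
    fit,
    numerator = data.frame(design = "blocked", location = "up"),
    denominator = data.frame(design = "random", location = "up")
  )
  # generator is symmetric across designs: ratio centred near 1
  expect_equal(same$median, 1, tolerance = 0.3)
  horiz <- contrast_ratio(
    fit,
    numerator = data.frame(design = "blocked", location = c("left", "right")),
    denominator = data.frame(design = "blocked", location = c("up", "down"))
  )
  expect_length(horiz$draws, n_draws(fit))
  expect_true(horiz$p_gt_1 >= 0 && horiz$p_gt_1 <= 1)
  # identical pools are rejected
  expect_error(
    contrast_ratio(fit,
                   numerator = data.frame(design = "blocked", location = "up"),
                   denominator = data.frame(design = "blocked", location = "up")),
    "overlap"
  )
  # geometric pooling of identical cells is the cell itself
  one <- pool <- crowdasym:::pool_ioa_draws(
    fit, tibble::tibble(design = "precued", location = "left"), "geometric"
  )
  expect_equal(one, ioa_draws(fit, "precued", "left"))
})

test_that("simulated populations propagate individual differences", {
  fit <- demo_fit()
  pop <- simulate_population(fit, n_participants = 400, seed = 6)
  expect_equal(nrow(pop$summary), 12)
  expect_equal(nrow(pop$participants), 400 * 12)
  # determinism under the seed
  pop2 <- simulate_population(fit, n_participants = 400, seed = 6)
  expect_identical(pop$summary, pop2$summary)
  # generator IOA 2.5 with ~0.07 log10 units of observer spread: most of the
  # population shows the asymmetry
  expect_true(all(pop$summary$prop_gt_1 > 0.9))
  # zero random-effect SDs collapse every participant onto its posterior draw
  frozen <- fit
  frozen$draws$sd_b[, c("fl_inward", "fl_outward")] <- 0
  pop0 <- simulate_population(frozen, n_participants = 50, seed = 7)
  draws_by_cell <- ioa_draws(frozen, "blocked", "up")
  got <- pop0$participants[pop0$participants$design == "blocked" &
                             pop0$participants$location == "up", ]
  expect_true(all(got$ioa %in% draws_by_cell))
})
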