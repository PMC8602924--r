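test_that("the dummy coding activates the documented columns", {
  fx <- fixed_row <- function(d, l, f) {
    m <- crowdasym:::fixed_design_matrix(
      tibble::tibble(design = d, location = l, flanker = f)
    )$X
    colnames(m)[m[1, ] == 1]
  }
  expect_equal(fixed_row("blocked", "up", "none"), "loc_up")
  expect_setequal(
    fixed_row("random", "left", "outward"),
    c("loc_left", "fl_outward", "des_random", "loc_left:fl_outward",
      "loc_left:des_random", "fl_outward:des_random",
      "loc_left:fl_outward:des_random")
  )
})

test_that("the 36-column fixed-effect matrix has full rank over the cell grid", {
  X <- crowdasym:::fixed_design_matrix(condition_cells())$X
  expect_equal(dim(X), c(36, 36))
  expect_equal(qr(X)$rank, 36)
})

test_that("the model frame drops flagged rows and validates its input", {
  tb <- quick_threshold_table(n_participants = 3, seed = 4)
  tb$excluded[1:5] <- TRUE
  frame <- build_design_matrix(tb)
  expect_equal(nrow(frame$X), nrow(tb) - 5)
  expect_equal(ncol(frame$Z), 8)
  expect_equal(length(frame$pid), nrow(frame$X))
  expect_error(build_design_matrix(tb[0, ]), "no rows")
  bad <- tb
  bad$location <- "center"
  expect_error(build_design_matrix(bad), "unknown location")
  # duplicate a retained (non-excluded) row
  expect_error(build_design_matrix(rbind(tb, tb[10, ])), "more than one row")
})

test_that("prior moments follow the term classes", {
  frame <- build_design_matrix(quick_threshold_table(2, seed = 1))
  pm <- crowdasym:::prior_moments(frame$classes, ioa_priors())
  expect_equal(unname(pm$mean[1:4]), rep(1, 4)) # location intercepts N(1,2)
  expect_equal(unname(pm$sd[1:4]), rep(2, 4))
  expect_equal(unname(pm$mean[5:6]), rep(1, 2)) # flanker mains N(1,0.5)
  expect_equal(unname(pm$sd[5:6]), rep(0.5, 2))
  expect_true(all(pm$mean[7:36] == 0))        # everything else N(0,1)
  expect_true(all(pm$sd[7:36] == 1))
})

test_that("prior predictive draws are positive, seeded, and report the HDI", {
  pp <- prior_predictive(n_draws = 20000, seed = 3)
  expect_true(all(pp$draws > 0))
  expect_equal(pp$mass, 0.75)
  expect_lt(pp$hdi[1], pp$hdi[2])
  # stability across seeds: upper HDI bound within 10% on the log scale
  pp2 <- prior_predictive(n_draws = 20000, seed = 4)
  expect_equal(log(pp$hdi[["upper"]]), log(pp2$hdi[["upper"]]), tolerance = 0.1)
  # degenerate priors collapse to exp(prior mean); e.g. an unflanked cell -> e^1
  tight <- ioa_priors(location_sd = 1e-9, flanker_sd = 1e-9, other_sd = 1e-9,
                      resid_scale = 1e-12)
  # cell log-means collapse to 1 (unflanked) or 1 + 1 = 2 (flanked)
  d <- prior_predictive(n_draws = 2000, priors = tight, seed = 5)$draws
  expect_true(all(abs(log(d) - round(log(d))) < 1e-3))
  expect_setequal(round(sort(unique(round(log(d), 3)))), c(1, 2))
})

test_that("the fit recovers known cell thresholds and is seed-deterministic", {
  tb <- demo_table()
  fit <- demo_fit()
  expect_s3_class(fit, "ioa_fit")
  expect_equal(n_draws(fit), fit$mcmc$chains * fit$mcmc$iter)
  expect_equal(nrow(fit$diagnostics), 36 + 8 + 1)
  expect_true(all(is.finite(fit$diagnostics$ess)))

  # posterior medians of cell thresholds near the generating truth:
  # demo population has unflanked 0.6, cf_inward 2, ioa 2.5
  cells <- condition_cells()
  pred <- vapply(seq_len(nrow(cells)), function(i) {
    median(cell_threshold_draws(fit, cells$design[i], cells$location[i],
                                cells$flanker[i]))
  }, numeric(1))
  truth <- ifelse(cells$flanker == "none", 0.6,
                  ifelse(cells$flanker == "inward", 1.2, 3.0))
  expect_true(mean(abs(log10(pred) - log10(truth)) < 0.15) >= 0.95)

  # rerun with the identical seed: identical draws
  refit <- suppressWarnings(fit_ioa(tb, preset = "smoke", seed = 11))
  expect_identical(fit$draws$beta, refit$draws$beta)
  expect_identical(fit$draws$sigma, refit$draws$sigma)
})

test_that("single-chain fits are refused", {
  expect_error(fit_ioa(quick_threshold_table(2, seed = 2), chains = 1),
               "2 chains")
})

test_that("Bayesian R-squared matches the generator's variance ratio", {
  # build data straight from the model: known signal and noise variances
  withr::with_seed(99, {
    n_obs <- 40
    cells <- condition_cells()
    eta_pop <- log(ifelse(cells$flanker == "none", 0.6,
                          ifelse(cells$flanker == "inward", 1.2, 3.0)))
    sigma <- 0.25
    tb <- tidyr::expand_grid(participant = seq_len(n_obs), cells)
    tb$threshold_deg <- exp(rep(eta_pop, n_obs) + rnorm(nrow(tb), 0, sigma))
    tb$sd_log10 <- 0.05
  })
  fit <- suppressWarnings(
    fit_ioa(apply_exclusion(tb), preset = "smoke", seed = 21)
  )
  r2 <- bayes_r2(fit)
  analytic <- var(eta_pop) * 35 / 36 / (var(eta_pop) * 35 / 36 + sigma^2)
  expect_equal(median(r2), analytic, tolerance = 0.05)
  expect_true(all(r2 > 0 & r2 < 1))
})

test_that("tidy and glance summarise the fit in broom conventions", {
  fit <- demo_fit()
  td <- tidy(fit)
  expect_true(all(c("term", "estimate", "std.error", "conf.low", "conf.high")
                  %in% names(td)))
  expect_equal(nrow(td), 36 + 8 + 1)
  expect_true(all(td$conf.low <= td$estimate & td$estimate <= td$conf.high))
  gl <- glance(fit)
  expect_equal(gl$nobs, sum(!demo_table()$excluded))
  expect_equal(gl$n_participants, 8)
  expect_gt(gl$r.squared, 0.5) # generator is strongly structured
})
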