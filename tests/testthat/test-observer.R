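test_that("the psychometric function hits the threshold criterion exactly", {
  pp <- psychometric_params()
  expect_equal(p_correct(0.5, 0.5, pp), 0.5, tolerance = 1e-9)
  expect_equal(p_correct(1.1, 1.1, pp), 0.5, tolerance = 1e-9)
  # criterion holds for other parameterisations too
  pp2 <- psychometric_params(guess_rate = 0.25, slope_beta = 2,
                             lapse_rate = 0.02, threshold_criterion = 0.6)
  expect_equal(p_correct(2, 2, pp2), 0.6, tolerance = 1e-9)
})

test_that("asymptotes match the closed form evaluated independently", {
  pp <- psychometric_params()
  # independent offset solve by root finding on the closed form
  psi_raw <- function(d, eps) {
    pp$lapse_rate * pp$guess_rate +
      (1 - pp$lapse_rate) *
        (1 - (1 - pp$guess_rate) * exp(-10^(pp$slope_beta * d + eps)))
  }
  eps <- uniroot(function(e) psi_raw(0, e) - 0.5, c(-5, 5), tol = 1e-12)$root
  expect_equal(pp$offset_epsilon, eps, tolerance = 1e-8)
  # guess-dominated floor as size -> 0
  expect_equal(p_correct(1e-6, 0.5, pp), pp$guess_rate, tolerance = 1e-3)
  # upper value at 10x threshold from the closed form
  expect_equal(p_correct(5, 0.5, pp), psi_raw(1, eps), tolerance = 1e-12)
  # lapse-limited ceiling
  expect_equal(p_correct(1e6, 0.5, pp),
               1 - pp$lapse_rate * (1 - pp$guess_rate), tolerance = 1e-9)
})

test_that("p_correct is monotone and depends only on the size/threshold ratio", {
  pp <- psychometric_params()
  sizes <- 10^seq(-1.5, 1, length.out = 60)
  p <- p_correct(sizes, 0.5, pp)
  expect_true(all(diff(p) >= 0))      # nondecreasing everywhere ...
  mid <- p_correct(10^seq(-0.6, -0.1, length.out = 30), 0.5, pp)
  expect_true(all(diff(mid) > 0))     # ... strictly so away from saturation
  thresholds <- 10^seq(-1, 1, length.out = 40)
  p2 <- p_correct(0.8, thresholds, pp)
  expect_true(all(diff(p2) <= 0))
  for (k in c(0.1, 3, 42)) {
    expect_equal(p_correct(k * 0.7, k * 0.5, pp), p_correct(0.7, 0.5, pp),
                 tolerance = 1e-12)
  }
  expect_error(p_correct(-1, 0.5, pp), "positive")
  expect_error(p_correct(0.5, 0, pp), "positive")
})

test_that("zero-variance populations collapse to the population truth", {
  cfg <- population_config(
    n_participants = 3, sd_intercept = 0, sd_location = 0,
    sd_flanker = 0, sd_design = 0
  )
  truths <- sample_population(cfg, seed = 1)
  expect_equal(nrow(truths), 3 * 36)
  none <- truths$true_threshold_deg[truths$flanker == "none"]
  expect_true(all(abs(none - 0.6) < 1e-12))
  inward <- truths$true_threshold_deg[truths$flanker == "inward"]
  expect_true(all(abs(inward - 1.2) < 1e-12))
  outward <- truths$true_threshold_deg[truths$flanker == "outward"]
  expect_true(all(abs(outward - 3.0) < 1e-12))
})

test_that("unit IOA makes outward and inward truths identical", {
  # inward/outward observer offsets are independent draws, so symmetry of
  # the truths themselves requires sd_flanker = 0
  cfg <- population_config(n_participants = 4, true_ioa = 1, sd_flanker = 0)
  truths <- sample_population(cfg, seed = 2)
  wide <- tidyr::pivot_wider(
    truths[truths$flanker != "none",
           c("participant", "design", "location", "flanker", "true_threshold_deg")],
    names_from = "flanker", values_from = "true_threshold_deg"
  )
  expect_equal(wide$outward, wide$inward, tolerance = 1e-12)
})

test_that("between-observer spread matches the configured SD", {
  cfg <- population_config(n_participants = 600)
  truths <- sample_population(cfg, seed = 3)
  # blocked/up/none activates only the intercept offset (SD 0.1 log10 units)
  cell <- truths$true_threshold_deg[truths$cell == "blocked/up/none"]
  expect_equal(sd(log10(cell)), 0.1, tolerance = 0.2 * 0.1)
  # random/down/outward adds location, flanker and design offsets
  cell2 <- truths$true_threshold_deg[truths$cell == "random/down/outward"]
  expect_equal(sd(log10(cell2)), sqrt(0.1^2 + 3 * 0.05^2),
               tolerance = 0.2 * sqrt(0.1^2 + 3 * 0.05^2))
})

test_that("per-cell tables of crowding factor and IOA are honoured", {
  cf_tab <- unique(condition_cells()[, c("design", "location")])
  cf_tab$cf_inward <- ifelse(cf_tab$location == "left", 3, 2)
  cfg <- population_config(n_participants = 1, true_cf_inward = cf_tab,
                           sd_intercept = 0, sd_location = 0,
                           sd_flanker = 0, sd_design = 0)
  truths <- sample_population(cfg, seed = 1)
  left_in <- truths$true_threshold_deg[truths$cell == "blocked/left/inward"]
  expect_equal(left_in, 0.6 * 3, tolerance = 1e-12)
  expect_error(population_config(true_cf_inward = cf_tab[-1, ]), "cover all 12")
})

test_that("trial simulation is Bernoulli with the psychometric probability", {
  pp <- psychometric_params()
  hits <- withr::with_seed(5, simulate_trial(rep(0.5, 10000), 0.5, pp))
  expect_equal(mean(hits), 0.5, tolerance = 0.02)
  # replay under the same seed gives the identical sequence
  a <- withr::with_seed(9, simulate_trial(rep(0.7, 50), 0.5, pp))
  b <- withr::with_seed(9, simulate_trial(rep(0.7, 50), 0.5, pp))
  expect_identical(a, b)
  # a stimulus far above threshold is almost always identified
  big <- withr::with_seed(6, simulate_trial(rep(1e5, 2000), 0.5,
                                            psychometric_params(lapse_rate = 1e-9)))
  expect_true(mean(big) > 0.99)
})
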