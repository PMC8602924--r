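#' Priors for the multilevel lognormal threshold model
#'
#' Informed, conservative priors on the natural-log threshold scale:
#'
#' * the four location intercepts (unflanked thresholds) get Normal(1, 2);
#' * the two flanker main effects (inward, outward) get Normal(1, 0.5) —
#'   flankers are expected to raise thresholds, and symmetrically so a
#'   priori, which is deliberately agnostic about the asymmetry under study;
#' * design main effects and every interaction get Normal(0, 1);
#' * each random-effect SD gets half-Cauchy(0, 10);
#' * the residual SD gets half-Cauchy(0, 1).
#'
#' @param location_mean,location_sd Normal prior on the location intercepts.
#' @param flanker_mean,flanker_sd Normal prior on the flanker main effects.
#' @param other_mean,other_sd Normal prior on all other fixed effects.
#' @param ranef_scale Half-Cauchy scale for random-effect SDs.
#' @param resid_scale Half-Cauchy scale for the residual SD.
#' @return An object of class `ioa_priors`.
#' @examples
#' ioa_priors()
#' @export
ioa_priors <- function(location_mean = 1, location_sd = 2,
                       flanker_mean = 1, flanker_sd = 0.5,
                       other_mean = 0, other_sd = 1,
                       ranef_scale = 10, resid_scale = 1) {
  if (any(c(location_sd, flanker_sd, other_sd, ranef_scale, resid_scale) <= 0)) {
    abort("all prior scales must be positive")
  }
  structure(
    list(
      location_mean = location_mean, location_sd = location_sd,
      flanker_mean = flanker_mean, flanker_sd = flanker_sd,
      other_mean = other_mean, other_sd = other_sd,
      ranef_scale = ranef_scale, resid_scale = resid_scale
    ),
    class = "ioa_priors"
  )
}

# Fixed-effect design matrix for arbitrary (design, location, flanker) rows.
# Dummy coding: location enters as four cell intercepts (no global
# intercept); flanker (reference none) and design (reference blocked) as
# dummies; interactions involving location use location reference "up".
# 4 + 2 + 2 + 6 + 6 + 4 + 12 = 36 columns, full rank over the 36 cells.
fixed_design_matrix <- function(df) {
  check_levels(df$design, design_levels, "design")
  check_levels(df$location, location_levels, "location")
  check_levels(df$flanker, flanker_levels, "flanker")
  loc <- as.character(df$location)
  fl <- as.character(df$flanker)
  des <- as.character(df$design)

  cols <- list()
  classes <- character(0)
  add <- function(name, x, cls) {
    cols[[name]] <<- as.numeric(x)
    classes[name] <<- cls
  }
  for (l in location_levels) add(paste0("loc_", l), loc == l, "location")
  for (f in c("inward", "outward")) add(paste0("fl_", f), fl == f, "flanker")
  for (d in c("precued", "random")) add(paste0("des_", d), des == d, "other")
  for (l in location_levels[-1]) for (f in c("inward", "outward")) {
    add(paste0("loc_", l, ":fl_", f), loc == l & fl == f, "other")
  }
  for (l in location_levels[-1]) for (d in c("precued", "random")) {
    add(paste0("loc_", l, ":des_", d), loc == l & des == d, "other")
  }
  for (f in c("inward", "outward")) for (d in c("precued", "random")) {
    add(paste0("fl_", f, ":des_", d), fl == f & des == d, "other")
  }
  for (l in location_levels[-1]) for (f in c("inward", "outward")) {
    for (d in c("precued", "random")) {
      add(paste0("loc_", l, ":fl_", f, ":des_", d),
          loc == l & fl == f & des == d, "other")
    }
  }
  X <- do.call(cbind, cols)
  list(X = X, classes = classes)
}

# random-effect design: intercept + each main-effect dummy
ranef_design_matrix <- function(df) {
  loc <- as.character(df$location)
  fl <- as.character(df$flanker)
  des <- as.character(df$design)
  cbind(
    intercept = rep(1, nrow(df)),
    loc_down = as.numeric(loc == "down"),
    loc_left = as.numeric(loc == "left"),
    loc_right = as.numeric(loc == "right"),
    fl_inward = as.numeric(fl == "inward"),
    fl_outward = as.numeric(fl == "outward"),
    des_precued = as.numeric(des == "precued"),
    des_random = as.numeric(des == "random")
  )
}

#' Build the model frame for the threshold regression
#'
#' Drops rows flagged by [apply_exclusion()] and assembles the fixed- and
#' random-effect design matrices. Fixed effects: four location intercepts,
#' inward/outward flanker dummies, precued/random design dummies, and all
#' two- and three-way interaction dummies (36 columns; every one of the 36
#' cell means is a sum of active columns). Random effects: by-participant
#' intercept plus each main-effect dummy (8 columns).
#'
#' @param table Threshold table (`participant, design, location, flanker,
#'   threshold_deg, sd_log10`, optionally `excluded`).
#' @return An object of class `ioa_modelframe`: the retained data, `X`, `Z`,
#'   the participant index `pid`, participant labels, and per-column prior
#'   classes.
#' @examples
#' truths <- sample_population(population_config(n_participants = 2), seed = 1)
#' tb <- dplyr::mutate(truths, threshold_deg = true_threshold_deg, sd_log10 = 0.05)
#' frame <- build_design_matrix(apply_exclusion(tb))
#' dim(frame$X)
#' @export
build_design_matrix <- function(table) {
  needed <- c("participant", "design", "location", "flanker", "threshold_deg")
  missing <- setdiff(needed, names(table))
  if (length(missing) > 0) {
    abort(paste("threshold table lacks column(s):", paste(missing, collapse = ", ")))
  }
  if ("excluded" %in% names(table)) table <- table[!table$excluded, ]
  if (nrow(table) == 0) abort("no rows left after exclusion")
  if (any(table$threshold_deg <= 0)) abort("thresholds must be positive")
  check_levels(table$design, design_levels, "design")
  check_levels(table$location, location_levels, "location")
  check_levels(table$flanker, flanker_levels, "flanker")
  if (anyDuplicated(table[, c("participant", "design", "location", "flanker")])) {
    abort("more than one row per (participant, cell)")
  }
  fx <- fixed_design_matrix(table)
  participants <- sort(unique(table$participant))
  structure(
    list(
      data = tibble::as_tibble(table),
      X = fx$X,
      classes = fx$classes,
      Z = ranef_design_matrix(table),
      pid = match(table$participant, participants),
      participants = participants
    ),
    class = "ioa_modelframe"
  )
}

prior_moments <- function(classes, priors) {
  mean <- ifelse(classes == "location", priors$location_mean,
                 ifelse(classes == "flanker", priors$flanker_mean, priors$other_mean))
  sd <- ifelse(classes == "location", priors$location_sd,
               ifelse(classes == "flanker", priors$flanker_sd, priors$other_sd))
  list(mean = mean, sd = sd)
}

ioa_jags_model <- "
model {
  for (n in 1:N) {
    z[n] ~ dnorm(eta[n], tau)
    eta[n] <- inprod(X[n, ], beta) + inprod(Zr[n, ], b[pid[n], ])
  }
  for (p in 1:P) { beta[p] ~ dnorm(prior_mean[p], prior_prec[p]) }
  for (j in 1:J) {
    for (k in 1:K) { b[j, k] ~ dnorm(0, prec_b[k]) }
  }
  for (k in 1:K) {
    sd_b[k] ~ dt(0, ranef_prec, 1) T(0, )
    prec_b[k] <- 1 / (sd_b[k] * sd_b[k])
  }
  sigma ~ dt(0, resid_prec, 1) T(0, )
  tau <- 1 / (sigma * sigma)
}"

#' MCMC presets
#'
#' `smoke`: 2 chains, 500 adaptation + 500 warmup + 500 retained iterations —
#' minutes on one core, adequate for pipeline checks. `full`: 4 chains,
#' 1000 + 1000 + 2000 — the scale used for reported summaries.
#'
#' @param preset `"smoke"` or `"full"`.
#' @return A list with `chains, adapt, warmup, iter`.
#' @export
mcmc_preset <- function(preset = c("smoke", "full")) {
  preset <- match.arg(preset)
  switch(preset,
    smoke = list(chains = 2L, adapt = 500L, warmup = 500L, iter = 500L),
    full = list(chains = 4L, adapt = 1000L, warmup = 1000L, iter = 2000L)
  )
}

#' Fit the multilevel lognormal threshold model
#'
#' Thresholds are modelled as lognormal: `log(threshold) ~ Normal(eta,
#' sigma)` with `eta` a full three-way factorial in design, location and
#' flanker (fixed effects; see [build_design_matrix()]) plus by-participant
#' random intercepts and main-effect deviations, under the priors of
#' [ioa_priors()]. Fitting the normal model to `log(threshold)` yields the
#' identical posterior to the lognormal likelihood (the Jacobian is
#' constant in the parameters). Sampling is by Gibbs/slice MCMC with the
#' `glm` samplers enabled; draws are deterministic given `seed`.
#'
#' Convergence is summarised by split-chain R-hat and effective sample size
#' per monitored parameter; a warning (never a silent pass) is issued when
#' any R-hat exceeds 1.01.
#'
#' @param table Threshold table; rows with `excluded = TRUE` are dropped.
#' @param preset MCMC preset name, see [mcmc_preset()].
#' @param priors An [ioa_priors()].
#' @param seed Integer seed (drives every chain's RNG).
#' @param chains,adapt,warmup,iter Optional overrides of the preset; at
#'   least 2 chains are required for diagnostics.
#' @param quiet Suppress the sampler's progress output.
#' @return An object of class `ioa_fit` holding the posterior draws
#'   (`draws$beta`: draws x 36 fixed effects; `draws$b`: draws x participants
#'   x 8; `draws$sd_b`: draws x 8; `draws$sigma`), the model frame,
#'   diagnostics, and the MCMC configuration.
#' @seealso [tidy()], [glance()], [bayes_r2()], [ioa_draws()], [ioa_table()]
#' @export
fit_ioa <- function(table, preset = "smoke", priors = ioa_priors(), seed = 1L,
                    chains = NULL, adapt = NULL, warmup = NULL, iter = NULL,
                    quiet = TRUE) {
  mc <- mcmc_preset(preset)
  mc$chains <- chains %||% mc$chains
  mc$adapt <- adapt %||% mc$adapt
  mc$warmup <- warmup %||% mc$warmup
  mc$iter <- iter %||% mc$iter
  if (mc$chains < 2) abort("at least 2 chains are required for convergence diagnostics")

  frame <- build_design_matrix(table)
  P <- ncol(frame$X)
  K <- ncol(frame$Z)
  J <- length(frame$participants)
  pm <- prior_moments(frame$classes, priors)

  rjags::load.module("glm", quiet = TRUE)
  inits <- lapply(seq_len(mc$chains), function(ch) {
    list(
      .RNG.name = "base::Mersenne-Twister",
      .RNG.seed = as.integer((as.double(seed) * 1009 + ch) %% 2147483646 + 1)
    )
  })
  data <- list(
    z = log(frame$data$threshold_deg),
    X = frame$X, Zr = frame$Z, pid = frame$pid,
    N = nrow(frame$X), P = P, J = J, K = K,
    prior_mean = pm$mean, prior_prec = 1 / pm$sd^2,
    ranef_prec = 1 / priors$ranef_scale^2,
    resid_prec = 1 / priors$resid_scale^2
  )
  run <- function() {
    jm <- rjags::jags.model(textConnection(ioa_jags_model), data = data,
                            inits = inits, n.chains = mc$chains,
                            n.adapt = mc$adapt, quiet = quiet)
    stats::update(jm, mc$warmup, progress.bar = "none")
    rjags::coda.samples(jm, c("beta", "b", "sd_b", "sigma"), n.iter = mc$iter,
                        progress.bar = "none")
  }
  samples <- tryCatch(run(), error = function(e) {
    abort(paste("MCMC sampling failed:", conditionMessage(e)))
  })

  draws_mat <- do.call(rbind, lapply(samples, as.matrix))
  D <- nrow(draws_mat)
  beta <- draws_mat[, sprintf("beta[%d]", seq_len(P)), drop = FALSE]
  colnames(beta) <- names(frame$classes)
  b <- array(
    draws_mat[, sprintf("b[%d,%d]", rep(seq_len(J), times = K),
                        rep(seq_len(K), each = J))],
    dim = c(D, J, K),
    dimnames = list(NULL, as.character(frame$participants), colnames(frame$Z))
  )
  sd_b <- draws_mat[, sprintf("sd_b[%d]", seq_len(K)), drop = FALSE]
  colnames(sd_b) <- colnames(frame$Z)

  term_names <- c(colnames(beta), paste0("sd_", colnames(sd_b)), "sigma")
  coda_names <- c(sprintf("beta[%d]", seq_len(P)), sprintf("sd_b[%d]", seq_len(K)), "sigma")
  gd <- try(coda::gelman.diag(samples[, coda_names, drop = FALSE],
                              multivariate = FALSE, autoburnin = FALSE),
            silent = TRUE)
  rhat <- if (inherits(gd, "try-error")) rep(NA_real_, length(coda_names)) else gd$psrf[, 1]
  ess <- coda::effectiveSize(samples[, coda_names, drop = FALSE])
  diagnostics <- tibble::tibble(term = term_names, rhat = as.numeric(rhat),
                                ess = as.numeric(ess))
  if (any(is.finite(diagnostics$rhat) & diagnostics$rhat > 1.01)) {
    warn(sprintf("R-hat exceeds 1.01 for %d parameter(s) (max %.3f); consider more iterations",
                 sum(diagnostics$rhat > 1.01, na.rm = TRUE),
                 max(diagnostics$rhat, na.rm = TRUE)))
  }

  structure(
    list(
      draws = list(beta = beta, b = b, sd_b = sd_b,
                   sigma = as.numeric(draws_mat[, "sigma"])),
      diagnostics = diagnostics,
      frame = frame,
      priors = priors,
      mcmc = c(mc, list(seed = as.integer(seed), preset = preset))
    ),
    class = "ioa_fit"
  )
}

#' @export
print.ioa_fit <- function(x, ...) {
  cat(sprintf(
    "<ioa_fit> %d thresholds, %d participants; %d draws (%d chains x %d); max R-hat %.3f\n",
    nrow(x$frame$data), length(x$frame$participants),
    nrow(x$draws$beta), x$mcmc$chains, x$mcmc$iter,
    max(x$diagnostics$rhat, na.rm = TRUE)
  ))
  invisible(x)
}

#' Number of posterior draws in a fit
#' @param fit An `ioa_fit`.
#' @return Integer draw count (chains x retained iterations).
#' @export
n_draws <- function(fit) nrow(fit$draws$beta)

# linear predictor for every retained row, per draw (N x D), including
# random effects
linear_predictor_draws <- function(fit) {
  eta <- fit$frame$X %*% t(fit$draws$beta)
  for (k in seq_len(ncol(fit$frame$Z))) {
    zk <- fit$frame$Z[, k]
    if (any(zk != 0)) {
      eta <- eta + zk * t(fit$draws$b[, fit$frame$pid, k])
    }
  }
  eta
}

#' Bayesian R-squared of the threshold model
#'
#' Per posterior draw, the variance of the linear predictor (fixed plus
#' random effects, on the log-threshold scale) over the retained rows,
#' divided by that variance plus the draw's residual variance.
#'
#' @param fit An `ioa_fit`.
#' @return Numeric vector, one R-squared per draw.
#' @examples
#' \donttest{
#' # median and 97% HPDI of R^2: median(r2); hdi(r2, 0.97)
#' }
#' @export
bayes_r2 <- function(fit) {
  eta <- linear_predictor_draws(fit)
  n <- nrow(eta)
  if (n < 2) abort("need at least two rows to compute R-squared")
  cm <- colMeans(eta)
  v <- (colSums(eta^2) - n * cm^2) / (n - 1)
  as.numeric(v / (v + fit$draws$sigma^2))
}

#' Prior predictive distribution of thresholds
#'
#' Samples thresholds implied by the priors alone: draw the 36 fixed effects
#' and the residual SD from their priors, pick a condition cell uniformly,
#' form the linear predictor and draw a lognormal threshold. By default the
#' random effects are left out; their heavy half-Cauchy(0, 10) scales make
#' the unconditional prior predictive extremely heavy-tailed, and the check
#' of interest is the plausible range of cell thresholds. Set
#' `include_random = TRUE` to add observer offsets.
#'
#' @param n_draws Number of prior draws.
#' @param priors An [ioa_priors()].
#' @param mass HDI mass to report (default 0.75).
#' @param include_random Include random-effect offsets.
#' @param seed Integer seed.
#' @return An object of class `ioa_prior_pred`: `draws` (thresholds, deg),
#'   `hdi` (named lower/upper), `mass`, `median`.
#' @examples
#' pp <- prior_predictive(n_draws = 20000, seed = 1)
#' pp$hdi
#' @export
prior_predictive <- function(n_draws = 1e5, priors = ioa_priors(), mass = 0.75,
                             include_random = FALSE, seed = 1L) {
  withr::local_seed(as.integer(seed))
  cells <- condition_cells()
  fx <- fixed_design_matrix(cells)
  pm <- prior_moments(fx$classes, priors)
  P <- ncol(fx$X)
  B <- matrix(rnorm(n_draws * P, rep(pm$mean, each = n_draws),
                    rep(pm$sd, each = n_draws)), n_draws, P)
  idx <- sample.int(nrow(cells), n_draws, replace = TRUE)
  eta <- rowSums(B * fx$X[idx, , drop = FALSE])
  if (include_random) {
    Zc <- ranef_design_matrix(cells)
    sds <- abs(rcauchy(n_draws * ncol(Zc), 0, priors$ranef_scale))
    off <- rnorm(n_draws * ncol(Zc), 0, sds)
    eta <- eta + rowSums(matrix(off, n_draws) * Zc[idx, , drop = FALSE])
  }
  sigma <- abs(rcauchy(n_draws, 0, priors$resid_scale))
  # the half-Cauchy tail can push log draws past the representable range;
  # clamp so the lognormal support (strictly positive, finite) is preserved
  log_draws <- rnorm(n_draws, eta, sigma)
  draws <- exp(pmin(pmax(log_draws, log(.Machine$double.xmin)),
                    log(.Machine$double.xmax)))
  structure(
    list(draws = draws, hdi = hdi(draws, mass), mass = mass,
         median = median(draws)),
    class = "ioa_prior_pred"
  )
}

#' @export
print.ioa_prior_pred <- function(x, ...) {
  cat(sprintf("<ioa_prior_pred> %d draws; median %.3g deg; %g%% HDI [%.3g, %.3g] deg\n",
              length(x$draws), x$median, 100 * x$mass, x$hdi[1], x$hdi[2]))
  invisible(x)
}

#' Tidy the fixed effects of a threshold model fit
#'
#' @param x An `ioa_fit`.
#' @param conf.level HPDI mass for the interval columns.
#' @param ... Unused.
#' @return A tibble with `term, estimate` (posterior median), `std.error`
#'   (posterior SD), `conf.low, conf.high` (HPDI) for each fixed effect,
#'   random-effect SD and the residual SD.
#' @method tidy ioa_fit
#' @export
tidy.ioa_fit <- function(x, conf.level = 0.97, ...) {
  mats <- c(
    as.list(as.data.frame(x$draws$beta, check.names = FALSE)),
    setNames(as.list(as.data.frame(x$draws$sd_b, check.names = FALSE)),
             paste0("sd_", colnames(x$draws$sd_b))),
    list(sigma = x$draws$sigma)
  )
  purrr::map_dfr(names(mats), function(term) {
    v <- mats[[term]]
    ci <- hdi(v, conf.level)
    tibble::tibble(term = term, estimate = median(v), std.error = sd(v),
                   conf.low = ci[1], conf.high = ci[2])
  })
}

#' One-row summary of a threshold model fit
#'
#' @param x An `ioa_fit`.
#' @param ... Unused.
#' @return A tibble: `nobs, n_participants, n_draws, max_rhat, min_ess,
#'   sigma` (posterior median residual SD) and `r.squared` (posterior median
#'   Bayesian R-squared).
#' @method glance ioa_fit
#' @export
glance.ioa_fit <- function(x, ...) {
  tibble::tibble(
    nobs = nrow(x$frame$data),
    n_participants = length(x$frame$participants),
    n_draws = n_draws(x),
    max_rhat = max(x$diagnostics$rhat, na.rm = TRUE),
    min_ess = min(x$diagnostics$ess, na.rm = TRUE),
    sigma = median(x$draws$sigma),
    r.squared = median(bayes_r2(x))
  )
}
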