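# Hierarchical models: R-hat, parameter recovery at reduced scale,
# structural invariants. Recovery at the full scale lives in
# test-acceptance.R.

test_that("rhat separates converged from split chains", {
  set.seed(51)
  white <- matrix(rnorm(4000), ncol = 2)
  expect_lt(abs(rhat(white) - 1), 0.05)
  same <- cbind(white[, 1], white[, 1])  # identical chains
  expect_lt(abs(rhat(same) - 1), 0.05)
  split <- cbind(rnorm(2000, 0, 1), rnorm(2000, 10, 1))
  expect_gt(rhat(split), 3)
  expect_error(rhat(matrix(rnorm(100), ncol = 1)), "2 chains")
})

test_that("the sampler converges on a normal target", {
  lp <- function(par) sum(dnorm(par, c(2, -1), c(1, 0.5), log = TRUE))
  fit <- pairflight:::amwg_sample(lp, c(a = 0, b = 0), n_chains = 4,
                                  warmup = 500, iter = 1000, seed = 3)
  s <- pairflight:::summarise_draws(fit$draws)
  expect_true(all(s$rhat <= 1.1))
  expect_equal(s$mean, c(2, -1), tolerance = 0.1)
  expect_equal(s$sd, c(1, 0.5), tolerance = 0.15)
})

make_small_world <- function(seed, n_birds = 8, n_solo = 6, n_pair = 6,
                             delta0 = 1.00, delta1 = 0) {
  birds <- make_birds(n_birds, seed = seed)
  truth <- truth_record(delta0_hz = delta0, delta1_hz_per_mm = delta1,
                        residual_sd_hz = 0.2)
  simulate_flight_summaries(birds, truth, n_solo = n_solo, n_pair = n_pair,
                            seed = seed, covariates = FALSE)
}

test_that("fit_pair_model recovers the pairing effect (reduced scale)", {
  fsm <- make_small_world(61)
  fit <- fit_pair_model(fsm, chains = 2, warmup = 800, iter = 800,
                        seed = 61)
  d0 <- fit$summary[fit$summary$parameter == "delta0", ]
  expect_lt(abs(d0$mean - 1.00), 0.2)
  expect_true(d0$q2.5 < 1.00 && 1.00 < d0$q97.5)
  d1 <- fit$summary[fit$summary$parameter == "delta1", ]
  expect_true(d1$q2.5 < 0 && 0 < d1$q97.5)
  expect_true(fit$converged)
})

test_that("without paired flights the pairing effect follows the prior", {
  fsm <- make_small_world(62, n_pair = 0)
  s0 <- sd(fsm$freq_hz)
  suppressWarnings(
    fit <- fit_pair_model(fsm, chains = 2, warmup = 600, iter = 600,
                          seed = 62))
  expect_match(paste(fit$notes, collapse = " "), "prior")
  d0 <- fit$summary[fit$summary$parameter == "delta0", ]
  expect_lt(abs(d0$mean), s0 / 3)
})

test_that("with solo data only, the likelihood reduces to mu_i + gamma X", {
  fsm <- make_small_world(63, n_pair = 0)
  fsm$airspeed <- rnorm(nrow(fsm), 19, 1)
  mdl <- pairflight:::pair_model_data(fsm, "freq_hz", "airspeed", NULL)
  par <- mdl$init
  par[grep("^mu\\[", names(par))] <- seq(5.2, 5.8,
                                         length.out = length(mdl$birds))
  par[grep("^gamma", names(par))] <- 0.03
  par[names(par) == "sigma"] <- log(0.2)
  # independent plain hierarchical regression likelihood
  mu <- par[grep("^mu\\[", names(par))]
  m <- mu[match(fsm$bird_id, mdl$birds)] +
    0.03 * (fsm$airspeed - mean(fsm$airspeed))
  expect_equal(mdl$log_lik(par),
               sum(dnorm(fsm$freq_hz, m, 0.2, log = TRUE)),
               tolerance = 1e-12)
})

test_that("mixing weights stay inside (0, 1) across draws", {
  fsm <- make_small_world(64)
  fit <- fit_pair_model(fsm, chains = 2, warmup = 400, iter = 400,
                        seed = 64)
  eta1 <- posterior_draws(fit, "eta1")
  etas <- posterior_draws(fit, "eta_s")
  for (dt in c(0, 1.5, 4)) {
    om <- plogis(eta1 + etas * dt)
    expect_true(all(om > 0 & om < 1))
  }
})

test_that("doubling flights per bird contracts the delta0 posterior", {
  sds <- sapply(1:4, function(r) {
    small <- make_small_world(70 + r, n_birds = 6, n_solo = 4, n_pair = 4)
    big <- make_small_world(80 + r, n_birds = 6, n_solo = 8, n_pair = 8)
    f1 <- suppressWarnings(fit_pair_model(small, chains = 2, warmup = 500,
                                          iter = 500, seed = r))
    f2 <- suppressWarnings(fit_pair_model(big, chains = 2, warmup = 500,
                                          iter = 500, seed = r))
    c(f1$summary$sd[f1$summary$parameter == "delta0"],
      f2$summary$sd[f2$summary$parameter == "delta0"])
  })
  expect_lt(mean(sds[2, ]), mean(sds[1, ]))
})

test_that("fit_spacing_model recovers intercept and slope (reduced)", {
  truth <- truth_record(delta0_hz = 1.21, spacing_slope_hz_per_m = -0.011)
  wbs <- simulate_wingbeat_sample(truth, n_pair = 20, n_solo = 20,
                                  beats_per_flight = 40, seed = 65)
  fit <- fit_spacing_model(wbs, chains = 2, warmup = 800, iter = 800,
                           seed = 65)
  s <- fit$summary
  expect_lt(abs(s$mean[s$parameter == "delta_0m"] - 1.21), 0.15)
  expect_lt(abs(s$mean[s$parameter == "slope"] + 0.011), 0.006)
  # linear predictor identity at 50 m
  pred <- spacing_effect_at(fit, 50)
  expect_equal(pred$mean,
               s$mean[s$parameter == "delta_0m"] +
                 50 * s$mean[s$parameter == "slope"],
               tolerance = 1e-9)
})

test_that("a zero spacing slope is covered by its interval", {
  truth <- truth_record(delta0_hz = 1.21, spacing_slope_hz_per_m = 0)
  wbs <- simulate_wingbeat_sample(truth, n_pair = 15, n_solo = 15,
                                  beats_per_flight = 30, seed = 66)
  fit <- fit_spacing_model(wbs, chains = 2, warmup = 600, iter = 600,
                           seed = 66)
  s <- fit$summary[fit$summary$parameter == "slope", ]
  expect_true(s$q2.5 < 0 && 0 < s$q97.5)
})

coupling_world <- function(beta, seed, n_pairs = 8, n_flights = 6,
                           sigma = 0.15) {
  set.seed(seed)
  do.call(rbind, lapply(seq_len(n_pairs), function(p) {
    wf <- rnorm(n_flights, 6.5, 0.3)
    data.frame(pair_id = sprintf("P%02d", p), freq_front = wf,
               freq_behind = 6.5 + beta * (wf - 6.5) +
                 rnorm(n_flights, 0, sigma))
  }))
}

test_that("fit_coupling_model recovers direct, absent, and negative", {
  f1 <- suppressWarnings(fit_coupling_model(coupling_world(1, 67),
                                            chains = 2, warmup = 1000,
                                            iter = 1000, seed = 67))
  b <- f1$summary[f1$summary$parameter == "beta", ]
  expect_true(b$mean > 0.8 && b$mean < 1.2)

  f0 <- suppressWarnings(fit_coupling_model(coupling_world(0, 68),
                                            chains = 2, warmup = 1000,
                                            iter = 1000, seed = 68))
  b0 <- f0$summary[f0$summary$parameter == "beta", ]
  expect_true(b0$q2.5 < 0 && 0 < b0$q97.5)

  fn <- suppressWarnings(fit_coupling_model(coupling_world(-0.24, 69),
                                            chains = 2, warmup = 1000,
                                            iter = 1000, seed = 69))
  bn <- fn$summary[fn$summary$parameter == "beta", ]
  expect_lt(abs(bn$mean - (-0.24)), 0.3)
})

test_that("fit_leadership_model: effect, null, and separation flag", {
  set.seed(71)
  s <- rnorm(40, 0, 2)
  strong <- data.frame(front = as.integer(s + rnorm(40, 0, 0.5) > 0),
                       tarsus_diff = s)
  f <- fit_leadership_model(strong, "tarsus_diff", chains = 2,
                            warmup = 800, iter = 800, seed = 71)
  b <- f$summary[f$summary$parameter == "beta", ]
  expect_gt(b$q2.5, 0)

  coin <- data.frame(front = rep(c(0L, 1L), 20),
                     tarsus_diff = rnorm(40, 0, 2))
  f2 <- fit_leadership_model(coin, "tarsus_diff", chains = 2,
                             warmup = 800, iter = 800, seed = 72)
  p_lead <- mean(plogis(posterior_draws(f2, "alpha")))
  expect_lt(abs(p_lead - 0.5), 0.1)
  b2 <- f2$summary[f2$summary$parameter == "beta", ]
  expect_true(b2$q2.5 < 0 && 0 < b2$q97.5)

  sep <- data.frame(front = as.integer(s > 0), tarsus_diff = s)
  f3 <- fit_leadership_model(sep, "tarsus_diff", chains = 2,
                             warmup = 400, iter = 400, seed = 73)
  expect_match(paste(f3$notes, collapse = " "), "separation")
})

test_that("relative_effects reproduces the printed percentages", {
  expect_equal(round(relative_effects(1.00, 5.48)$percent_mean, 1), 18.2)
  expect_equal(relative_effects(0, 5.48)$percent_mean, 0)
  expect_equal(round(relative_effects(-4.65, 20.68)$percent_mean, 1), -22.5)
  expect_error(relative_effects(1, 0), "non-zero")
  # draws are transformed endpoint-wise
  set.seed(74)
  x <- rnorm(4000, 1, 0.1)
  r <- relative_effects(x, 5.48)
  expect_equal(r$percent_mean, mean(x) / 5.48 * 100, tolerance = 1e-9)
  expect_lt(r$percent_q2.5, r$percent_mean)
})
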