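# Self-contained reproduction of the headline quantities: each function
# builds its input world from scratch (at the published effect sizes),
# runs the relevant pipeline stage, and measures the result. Used by
# scripts/acceptance.R and the acceptance tests.

#' Reproduce the upstroke-shortening measurement from constructed waves
#'
#' Builds 60 s noise-free two-segment dorsal waveforms (solo: 48.7 ms
#' downstroke, 133.8 ms upstroke; paired: upstroke shortened by
#' 28.63 ms), segments both with [detect_wingbeats()] and
#' [stroke_phases()], and returns the percentage change in median
#' upstroke duration.
#'
#' @param duration_s waveform length, seconds.
#' @return percent change (negative for a reduction).
#' @export
reproduce_upstroke_change <- function(duration_s = 60) {
  tt <- seq(0, duration_s, by = 1 / 200)
  wave <- function(down, up) {
    accel_trace(tt, two_segment_wave(tt, 1 / (down + up), 2.5, down),
                sample_rate_hz = 200)
  }
  up_med <- function(tr) {
    stats::median(stroke_phases(detect_wingbeats(tr))$up_ms)
  }
  solo <- up_med(wave(0.0487, 0.1338))
  paired <- up_med(wave(0.0487, 0.1338 - 0.02863))
  (paired - solo) / solo * 100
}

#' Recover the pairing effect on wingbeat frequency from synthetic medians
#'
#' Generates 20 birds (solo means N(5.48, 0.19^2)) with 12 solo and 12
#' paired flight medians each at a true pairing effect of +1.00 Hz
#' (no tarsus effect, residual SD 0.2 Hz), fits the hierarchical
#' pairing model, and returns the posterior mean of the effect.
#'
#' @param seed integer seed.
#' @param chains,warmup,iter MCMC budget (default 4 x 2000 + 2000).
#' @return list with `estimate` (posterior mean of delta0) and `fit`.
#' @export
reproduce_pairing_effect <- function(seed = 1L, chains = 4, warmup = 2000,
                                     iter = 2000) {
  birds <- make_birds(20, seed = seed)
  truth <- truth_record(delta0_hz = 1.00, delta1_hz_per_mm = 0,
                        residual_sd_hz = 0.2)
  fsm <- simulate_flight_summaries(birds, truth, n_solo = 12, n_pair = 12,
                                   seed = seed, covariates = FALSE)
  fit <- fit_pair_model(fsm, chains = chains, warmup = warmup,
                        iter = iter, seed = seed)
  list(estimate = fit$summary$mean[fit$summary$parameter == "delta0"],
       n = nrow(fsm), fit = fit)
}

#' Recover the per-metre spacing slope from synthetic wingbeats
#'
#' Simulates 100 wingbeats per flight for 50 paired and 50 solo flights
#' (pairing effect 1.21 Hz at 0 m, slope -0.011 Hz/m, spacing uniform
#' on [0, 50] m, per-flight effect SD 0.1 Hz), fits the wingbeat-level
#' spacing model, and returns the absolute posterior mean of the slope.
#'
#' @inheritParams reproduce_pairing_effect
#' @return list with `estimate` (|slope|), `n` and `fit`.
#' @export
reproduce_spacing_slope <- function(seed = 1L, chains = 4, warmup = 2000,
                                    iter = 2000) {
  truth <- truth_record(delta0_hz = 1.21, spacing_slope_hz_per_m = -0.011)
  wbs <- simulate_wingbeat_sample(truth, n_pair = 50, n_solo = 50,
                                  beats_per_flight = 100,
                                  flight_effect_sd = 0.1, seed = seed)
  fit <- fit_spacing_model(wbs, chains = chains, warmup = warmup,
                           iter = iter, seed = seed)
  list(estimate = abs(fit$summary$mean[fit$summary$parameter == "slope"]),
       n = nrow(wbs), fit = fit)
}

#' Recover the pairing effect on route accuracy from simulated tracks
#'
#' Simulates 12 solo tracks per bird for 20 birds and 12 paired releases
#' for each of the 10 pairs, with heading concentrations calibrated via
#' the Bessel ratio to expected route accuracies of 0.86 (solo) and
#' 0.92 (paired); computes [route_accuracy()] per flight and fits the
#' hierarchical pairing model on the accuracy response. Tracks are
#' noise-free (the calibration refers to the heading process itself)
#' and wind-free.
#'
#' @param seed integer seed.
#' @param n_solo,n_pair flights per bird per condition.
#' @param chains,warmup,iter MCMC budget.
#' @return list with `estimate` (posterior mean pairing effect), `n`
#'   and `fit`.
#' @export
reproduce_accuracy_effect <- function(seed = 1L, n_solo = 12, n_pair = 12,
                                      chains = 4, warmup = 2000,
                                      iter = 2000) {
  birds <- make_birds(20, seed = seed)
  truth <- truth_record(accuracy_solo = 0.86, accuracy_pair = 0.92)
  rows <- list(); r <- 0L
  sub_seed <- function(k) (as.integer(seed) + 7919L * k) %% 2100000000L
  k <- 0L
  for (b in seq_len(nrow(birds))) {
    for (fl in seq_len(n_solo)) {
      k <- k + 1L
      plan <- list(flight_id = sprintf("RS%03d", k), condition = "solo",
                   bird1 = birds$bird_id[b], wind_speed_ms = 0,
                   wind_dir_deg = 0)
      g <- simulate_track(plan, birds, truth, seed = sub_seed(k),
                          gps_jitter_sd = 0)[[1]]
      r <- r + 1L
      rows[[r]] <- data.frame(bird_id = birds$bird_id[b],
                              partner_id = NA_character_, is_pair = 0L,
                              tarsus_diff_mm = 0,
                              route_accuracy = route_accuracy(g, LOFT_SITE))
    }
  }
  for (p in seq_len(floor(nrow(birds) / 2))) {
    b1 <- 2 * p - 1; b2 <- 2 * p
    d_t <- abs(birds$tarsus_mm[b1] - birds$tarsus_mm[b2])
    for (fl in seq_len(n_pair)) {
      k <- k + 1L
      plan <- list(flight_id = sprintf("RP%03d", k), condition = "pair",
                   bird1 = birds$bird_id[b1], bird2 = birds$bird_id[b2],
                   wind_speed_ms = 0, wind_dir_deg = 0)
      g <- simulate_track(plan, birds, truth, seed = sub_seed(k),
                          gps_jitter_sd = 0)
      for (i in 1:2) {
        r <- r + 1L
        rows[[r]] <- data.frame(
          bird_id = birds$bird_id[if (i == 1) b1 else b2],
          partner_id = birds$bird_id[if (i == 1) b2 else b1],
          is_pair = 1L, tarsus_diff_mm = d_t,
          route_accuracy = route_accuracy(g[[i]], LOFT_SITE))
      }
    }
  }
  fsm <- do.call(rbind, rows)
  fit <- fit_pair_model(fsm, response = "route_accuracy",
                        chains = chains, warmup = warmup, iter = iter,
                        seed = seed)
  list(estimate = fit$summary$mean[fit$summary$parameter == "delta0"],
       n = nrow(fsm), fit = fit)
}
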