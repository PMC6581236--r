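# Synthetic-data generation with known ground truth, emulating a
# paired-release homing experiment: a registry of birds, a 4-phase
# flight schedule (solo / similar-sized pair / different-sized pair /
# solo), 5 Hz GPS tracks with a calibrated heading-error process, 200 Hz
# accelerometer traces built from a two-segment wingbeat waveform, and
# constant-within-flight weather.

#' Ground-truth generative parameters
#'
#' Collects every generative parameter of a synthetic dataset so that
#' parameter-recovery tests know the truth. Defaults are the effect
#' sizes of a paired-versus-solo pigeon release experiment: a +1.00 Hz
#' pairing effect on wingbeat frequency, no tarsus-difference effect, a
#' -0.011 Hz/m spacing slope, route accuracies of 0.86 solo and 0.92
#' paired, 2.5 g peak-to-peak dorsal acceleration, an upstroke occupying
#' 0.733 of the cycle (133.8 of 182.5 ms), and a 0.2 Hz residual SD on
#' flight-median frequency.
#'
#' @param delta0_hz pairing effect on wingbeat frequency, Hz.
#' @param delta1_hz_per_mm effect per mm absolute tarsus difference.
#' @param spacing_slope_hz_per_m per-metre frequency effect of
#'   horizontal spacing within a pair.
#' @param accuracy_solo,accuracy_pair expected route accuracy, in
#'   (-1, 1].
#' @param pp_accel_g peak-to-peak dorsal dynamic acceleration, g.
#' @param upstroke_frac fraction of the cycle from acceleration minimum
#'   to maximum, in (0, 1).
#' @param eta1,eta_s intercept/slope of the logistic mixing weight
#'   omega_i = plogis(eta1 + eta_s * |T_i - T_j|) (0/0 gives an even
#'   0.5/0.5 blend of the two solo frequencies).
#' @param covariate_effects named numeric vector gamma of covariate
#'   effects on frequency (names among `temp_c`, `humidity_pct`,
#'   `rho_air`, `airspeed`, `wind_support`, `crosswind`); applied to
#'   centred covariates. Default all zero.
#' @param residual_sd_hz residual SD sigma of flight-median frequency,
#'   Hz (>= 0).
#' @param spacing_mean_m,spacing_sd_m stationary mean/SD of the pair
#'   offset process (median spacing about 12 m by default).
#' @param seed integer seed recorded with the truth.
#' @return list of class `truth_record`.
#' @export
truth_record <- function(delta0_hz = 1.00, delta1_hz_per_mm = 0,
                         spacing_slope_hz_per_m = -0.011,
                         accuracy_solo = 0.86, accuracy_pair = 0.92,
                         pp_accel_g = 2.5, upstroke_frac = 133.8 / 182.5,
                         eta1 = 0, eta_s = 0,
                         covariate_effects = c(temp_c = 0, humidity_pct = 0,
                                               rho_air = 0, airspeed = 0),
                         residual_sd_hz = 0.2,
                         spacing_mean_m = 12, spacing_sd_m = 3.5,
                         seed = 1L) {
  acc <- c(accuracy_solo, accuracy_pair)
  if (any(acc <= -1 | acc > 1)) stop("accuracy values must lie in (-1, 1]")
  if (upstroke_frac <= 0 || upstroke_frac >= 1) {
    stop("upstroke_frac must lie in (0, 1)")
  }
  if (residual_sd_hz < 0) stop("residual_sd_hz must be >= 0")
  if (pp_accel_g <= 0) stop("pp_accel_g must be positive")
  structure(list(delta0_hz = delta0_hz,
                 delta1_hz_per_mm = delta1_hz_per_mm,
                 spacing_slope_hz_per_m = spacing_slope_hz_per_m,
                 accuracy_solo = accuracy_solo,
                 accuracy_pair = accuracy_pair,
                 pp_accel_g = pp_accel_g,
                 upstroke_frac = upstroke_frac,
                 eta1 = eta1, eta_s = eta_s,
                 covariate_effects = covariate_effects,
                 residual_sd_hz = residual_sd_hz,
                 spacing_mean_m = spacing_mean_m,
                 spacing_sd_m = spacing_sd_m,
                 seed = as.integer(seed)),
            class = "truth_record")
}

# reference values about which covariates are centred in the generator
COVARIATE_REF <- c(temp_c = 15, humidity_pct = 60, rho_air = 1.225,
                   airspeed = 19.1, wind_support = 0, crosswind = 0)

covariate_shift <- function(truth, covariates) {
  g <- truth$covariate_effects
  if (is.null(g) || length(g) == 0) return(0)
  tot <- 0
  for (nm in names(g)) {
    if (!is.null(covariates[[nm]])) {
      tot <- tot + g[[nm]] * (covariates[[nm]] - COVARIATE_REF[[nm]])
    }
  }
  tot
}

#' Generate a registry of synthetic birds
#'
#' Draws per-bird baseline (solo) wingbeat frequencies, tarsus lengths
#' and body masses from normal laws. Defaults give a population solo
#' frequency of 5.48 +/- 0.19 Hz.
#'
#' @param n number of birds (>= 1).
#' @param seed integer seed.
#' @param freq_mean_hz,freq_sd_hz population mean/SD of the solo
#'   wingbeat frequency.
#' @param tarsus_mean_mm,tarsus_sd_mm tarsus length distribution.
#' @param mass_mean_g,mass_sd_g body mass distribution.
#' @return data.frame with `bird_id`, `tarsus_mm`, `mass_g`,
#'   `solo_freq_hz`.
#' @export
make_birds <- function(n, seed = 1L, freq_mean_hz = 5.48, freq_sd_hz = 0.19,
                       tarsus_mean_mm = 33.5, tarsus_sd_mm = 1.5,
                       mass_mean_g = 450, mass_sd_g = 40) {
  if (n < 1) stop("n must be >= 1")
  if (freq_sd_hz < 0 || tarsus_sd_mm < 0 || mass_sd_g < 0) {
    stop("standard deviations must be >= 0")
  }
  set.seed(as.integer(seed))
  out <- data.frame(
    bird_id = sprintf("S%02d", seq_len(n)),
    tarsus_mm = pmax(1, stats::rnorm(n, tarsus_mean_mm, tarsus_sd_mm)),
    mass_g = pmax(1, stats::rnorm(n, mass_mean_g, mass_sd_g)),
    solo_freq_hz = stats::rnorm(n, freq_mean_hz, freq_sd_hz))
  bad <- out$solo_freq_hz <= 2 | out$solo_freq_hz >= 12
  if (any(bad)) stop("drawn solo frequencies fall outside (2, 12) Hz; ",
                     "check freq_mean_hz/freq_sd_hz")
  out
}

# default experiment geometry (release site and home loft)
RELEASE_SITE <- list(lat = 51 + 47 / 60 + 48.1 / 3600,
                     lon = -(1 + 25 / 60 + 3.3 / 3600))
LOFT_SITE <- list(lat = 51 + 46 / 60 + 58.2 / 3600,
                  lon = -(1 + 19 / 60 + 2.7 / 3600))

#' Build a 4-phase flight schedule
#'
#' Phase 1 and 4: solo releases of every bird. Phase 2: similar-sized
#' pairs (adjacent birds in tarsus order). Phase 3: different-sized
#' pairs (smallest with largest, and so on). Weather is drawn once per
#' flight (constant within the flight): wind speed uniform on
#' [0, `max_wind_ms`], direction uniform, temperature, humidity and
#' pressure from mild summer ranges.
#'
#' @param birds registry from [make_birds()].
#' @param flights_per_phase releases per bird per phase (default 6).
#' @param seed integer seed.
#' @param max_wind_ms release-condition cap on wind speed (default 7).
#' @param base_epoch POSIX epoch of the first release.
#' @return data.frame with one row per release and columns `flight_id`,
#'   `phase`, `condition`, `pair_id`, `bird1`, `bird2`,
#'   `release_epoch`, `wind_speed_ms`, `wind_dir_deg`, `temp_c`,
#'   `humidity_pct`, `pressure_hpa`.
#' @export
make_flight_plans <- function(birds, flights_per_phase = 6, seed = 1L,
                              max_wind_ms = 7, base_epoch = 1433151000) {
  set.seed(as.integer(seed) + 17L)
  n <- nrow(birds)
  ord <- order(birds$tarsus_mm)
  half <- floor(n / 2)
  similar <- lapply(seq_len(half), function(k) {
    ord[c(2 * k - 1, 2 * k)]
  })
  different <- lapply(seq_len(half), function(k) {
    c(ord[k], ord[n - k + 1])
  })
  rows <- list()
  fid <- 0L
  add <- function(phase, condition, b1, b2, pair_id) {
    fid <<- fid + 1L
    rows[[fid]] <<- data.frame(
      flight_id = sprintf("F%04d", fid), phase = phase,
      condition = condition, pair_id = pair_id,
      bird1 = b1, bird2 = b2,
      release_epoch = base_epoch + (fid - 1) * 3 * 3600,
      wind_speed_ms = stats::runif(1, 0, max_wind_ms),
      wind_dir_deg = stats::runif(1, 0, 360),
      temp_c = stats::runif(1, 12, 25),
      humidity_pct = stats::runif(1, 40, 90),
      pressure_hpa = stats::rnorm(1, 1013, 5))
  }
  for (phase in c(1L, 2L, 3L, 4L)) {
    for (rep in seq_len(flights_per_phase)) {
      if (phase %in% c(1L, 4L)) {
        for (b in birds$bird_id) add(phase, "solo", b, NA_character_, NA)
      } else {
        pairs <- if (phase == 2L) similar else different
        for (k in seq_along(pairs)) {
          p <- pairs[[k]]
          add(phase, "pair", birds$bird_id[p[1]], birds$bird_id[p[2]],
              sprintf("P%d_%02d", phase, k))
        }
      }
    }
  }
  do.call(rbind, rows)
}

#' Concentration of a von Mises heading error for a target accuracy
#'
#' Inverts the Bessel-function ratio \eqn{A(\kappa) = I_1(\kappa) /
#' I_0(\kappa)} numerically, so that i.i.d. von Mises heading errors
#' with the returned concentration have expected cosine equal to the
#' target route accuracy.
#'
#' @param accuracy target mean cosine, strictly inside (0, 1).
#' @return concentration parameter kappa.
#' @export
vm_concentration <- function(accuracy) {
  if (accuracy <= 0 || accuracy >= 1) {
    stop("accuracy target must lie strictly in (0, 1) for calibration")
  }
  bessel_ratio <- function(k) {
    if (k > 1e5) return(1 - 1 / (2 * k) - 1 / (8 * k^2))  # asymptotic
    besselI(k, 1, expon.scaled = TRUE) / besselI(k, 0, expon.scaled = TRUE)
  }
  stats::uniroot(function(k) bessel_ratio(k) - accuracy,
                 lower = 1e-8, upper = 1e7, tol = 1e-10)$root
}

#' Draw from a von Mises distribution (Best-Fisher rejection sampler)
#'
#' @param n number of draws.
#' @param kappa concentration (>= 0; 0 is uniform on the circle).
#' @return angles in radians, centred on zero.
#' @export
rvonmises <- function(n, kappa) {
  if (kappa < 1e-8) return(stats::runif(n, -pi, pi))
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  out <- numeric(n)
  got <- 0L
  while (got < n) {
    m <- n - got
    z <- cos(pi * stats::runif(m))
    f <- (1 + r * z) / (r + z)
    cc <- kappa * (r - f)
    u2 <- stats::runif(m)
    acc <- (cc * (2 - cc) - u2 > 0) | (log(cc / u2) + 1 - cc >= 0)
    k <- sum(acc)
    if (k > 0) {
      th <- sign(stats::runif(k) - 0.5) *
        acos(pmax(-1, pmin(1, f[acc])))
      out[got + seq_len(k)] <- th
      got <- got + k
    }
  }
  out
}

# one simulated trajectory: headings aim at the goal with the supplied
# heading-error sequence (radians); ground velocity = air velocity +
# wind; returns exact (noise-free) positions
steer_track <- function(start, goal, err, airspeed_ms, wind_e, wind_n,
                        dt, stop_radius_m = 40, max_steps = length(err)) {
  lat <- numeric(max_steps + 1)
  lon <- numeric(max_steps + 1)
  lat[1] <- start$lat; lon[1] <- start$lon
  i <- 1L
  while (i <= max_steps) {
    d_goal <- haversine_m(lat[i], lon[i], goal$lat, goal$lon)
    if (d_goal < stop_radius_m) break
    brg <- forward_azimuth(lat[i], lon[i], goal$lat, goal$lon)
    h <- (brg + err[i] * 180 / pi) * pi / 180
    ge <- airspeed_ms * sin(h) + wind_e
    gn <- airspeed_ms * cos(h) + wind_n
    step <- sqrt(ge^2 + gn^2) * dt
    gb <- atan2(ge, gn) * 180 / pi
    p <- destination_point(lat[i], lon[i], gb, step)
    lat[i + 1] <- p$lat; lon[i + 1] <- p$lon
    i <- i + 1L
  }
  list(lat = lat[seq_len(i)], lon = lon[seq_len(i)], n = i)
}

# mean-reverting (Ornstein-Uhlenbeck) offset process, exact discretisation
ou_path <- function(n, mu, sd, tau_s, dt) {
  a <- exp(-dt / tau_s)
  innov_sd <- sd * sqrt(1 - a^2)
  x <- numeric(n)
  x[1] <- stats::rnorm(1, mu, sd)
  for (i in seq_len(n - 1)) {
    x[i + 1] <- mu + a * (x[i] - mu) + stats::rnorm(1, 0, innov_sd)
  }
  x
}

#' Simulate GPS track(s) for one release
#'
#' Positions step at the fix rate from release towards the loft; each
#' step's air heading is the current goal bearing plus an i.i.d. von
#' Mises error whose concentration is calibrated (Bessel ratio,
#' [vm_concentration()]) so the expected cosine of the heading error
#' equals the target route accuracy; the ground velocity is the air
#' velocity plus the wind vector. For paired releases the two birds
#' share one heading-error sequence (a perfectly correlated heading
#' process, so both carry the calibrated accuracy) and the second bird
#' flies from a laterally offset start (default about 12 m) with a slow
#' mean-reverting station-keeping wiggle, which keeps time-matched
#' spacing well below 50 m. Optional GPS jitter is added as zero-mean
#' Gaussian noise per horizontal component.
#'
#' Note the accuracy calibration describes the noise-free trajectory;
#' with `gps_jitter_sd > 0` the measured route accuracy of the jittered
#' fixes is biased low at 5 Hz because jitter is comparable to the step
#' length.
#'
#' @param plan one row of [make_flight_plans()] (list or 1-row
#'   data.frame).
#' @param birds registry from [make_birds()].
#' @param truth a [truth_record()].
#' @param seed integer seed.
#' @param airspeed_ms solo airspeed, m/s.
#' @param airspeed_pair_delta added airspeed in paired flight, m/s.
#' @param fix_rate_hz GPS fix rate (default 5).
#' @param gps_jitter_sd GPS noise SD per component, metres (default
#'   1.5; set 0 for noise-free tracks).
#' @param release,loft release and goal coordinates (lists with `lat`,
#'   `lon`); defaults 7.06 km apart on a 282 degree loft-to-release
#'   bearing.
#' @param accuracy override for the target route accuracy (default:
#'   `truth$accuracy_solo` or `truth$accuracy_pair` by condition; a
#'   value of 1 gives a zero-error straight great circle).
#' @return list of [gps_track()] objects, one per bird on the release.
#' @export
simulate_track <- function(plan, birds, truth, seed = 1L,
                           airspeed_ms = 19.1, airspeed_pair_delta = 0.63,
                           fix_rate_hz = 5, gps_jitter_sd = 1.5,
                           release = RELEASE_SITE, loft = LOFT_SITE,
                           accuracy = NULL) {
  plan <- as.list(plan)
  set.seed(as.integer(seed))
  is_pair <- identical(plan$condition, "pair")
  if (is.null(accuracy)) {
    accuracy <- if (is_pair) truth$accuracy_pair else truth$accuracy_solo
  }
  if (accuracy <= 0 || accuracy > 1) {
    stop("accuracy target must lie in (0, 1]")
  }
  kappa <- if (accuracy >= 1) Inf else vm_concentration(accuracy)
  speed <- airspeed_ms + if (is_pair) airspeed_pair_delta else 0
  dt <- 1 / fix_rate_hz
  wdir_to <- ((plan$wind_dir_deg %||% 0) + 180) * pi / 180
  ws <- plan$wind_speed_ms %||% 0
  max_steps <- ceiling(3 * haversine_m(release$lat, release$lon,
                                       loft$lat, loft$lon) /
                         max(speed - ws, 2) / dt)
  err <- if (is.finite(kappa)) rvonmises(max_steps, kappa) else
    numeric(max_steps)
  lead <- steer_track(release, loft, err, speed,
                      ws * sin(wdir_to), ws * cos(wdir_to), dt)
  jitter <- function(lat, lon) {
    if (gps_jitter_sd <= 0) return(list(lat = lat, lon = lon))
    de <- stats::rnorm(length(lat), 0, gps_jitter_sd)
    dn <- stats::rnorm(length(lat), 0, gps_jitter_sd)
    list(lat = lat + dn / EARTH_RADIUS_M * 180 / pi,
         lon = lon + de / (EARTH_RADIUS_M * cos(lat * pi / 180)) * 180 / pi)
  }
  p1 <- jitter(lead$lat, lead$lon)
  out <- list(gps_track((seq_len(lead$n) - 1) * dt, p1$lat, p1$lon,
                        flight_id = plan$flight_id, bird_id = plan$bird1))
  if (is_pair) {
    # follower: same heading-error sequence, start and goal both shifted
    # by one offset vector (mostly behind, a little to the side), so the
    # pair flies parallel tracks at the configured spacing and the first
    # bird stays in front
    base_brg <- forward_azimuth(release$lat, release$lon, loft$lat, loft$lon)
    off_brg <- base_brg + 155
    fstart <- destination_point(release$lat, release$lon, off_brg,
                                truth$spacing_mean_m)
    fgoal <- destination_point(loft$lat, loft$lon, off_brg,
                               truth$spacing_mean_m)
    fol <- steer_track(list(lat = fstart$lat, lon = fstart$lon),
                       list(lat = fgoal$lat, lon = fgoal$lon), err,
                       speed, ws * sin(wdir_to), ws * cos(wdir_to), dt)
    n <- min(lead$n, fol$n)
    # slow station-keeping wiggle on top (zero-mean, 30 s relaxation)
    we <- ou_path(n, 0, truth$spacing_sd_m / 2, tau_s = 30, dt)
    wn <- ou_path(n, 0, truth$spacing_sd_m / 2, tau_s = 30, dt)
    lat2 <- fol$lat[seq_len(n)] + wn / EARTH_RADIUS_M * 180 / pi
    lon2 <- fol$lon[seq_len(n)] + we /
      (EARTH_RADIUS_M * cos(fol$lat[seq_len(n)] * pi / 180)) * 180 / pi
    p2 <- jitter(lat2, lon2)
    out[[2]] <- gps_track((seq_len(n) - 1) * dt, p2$lat, p2$lon,
                          flight_id = plan$flight_id, bird_id = plan$bird2)
  }
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

two_segment_wave <- function(t_s, freq_hz, pp_g, down_s) {
  period <- 1 / freq_hz
  up_s <- period - down_s
  if (up_s <= 0) stop("downstroke duration exceeds the wingbeat period")
  ph <- t_s %% period
  amp <- pp_g / 2
  ifelse(ph < down_s,
         amp * cos(pi * ph / down_s),
         -amp * cos(pi * (ph - down_s) / up_s))
}

#' Simulate accelerometer trace(s) for one release
#'
#' The flight-level wingbeat frequency follows the generative model:
#' solo, \eqn{\mu_i + \gamma X + \epsilon}; paired, \eqn{\delta_0 +
#' \delta_1 |T_i - T_j| + s \cdot d + \omega_i \mu_i + (1 - \omega_i)
#' \mu_j + \gamma X + \epsilon} with spacing d and slope s. The dorsal
#' (Z) channel is 1 g static plus a two-segment waveform per wingbeat:
#' a half-cosine from maximum to minimum over the downstroke duration
#' and a half-cosine back over the upstroke, so the two phase durations
#' are exactly controllable and sum to the period. The downstroke
#' duration is held at its solo value (`(1 - upstroke_frac) / mu_i`), so
#' condition-driven frequency changes shorten the upstroke only.
#'
#' @param plan one row of [make_flight_plans()].
#' @param birds registry from [make_birds()].
#' @param truth a [truth_record()].
#' @param seed integer seed.
#' @param duration_s trace length, seconds (default 60).
#' @param sample_rate_hz sampling rate (default 200).
#' @param noise_sd white sensor noise SD on the Z channel, g (default 0).
#' @param spacing_m horizontal spacing entering the frequency equation
#'   for paired flights (default `truth$spacing_mean_m`).
#' @param waveform `"two_segment"` (default) or `"sinusoid"` (pure
#'   harmonic, for closed-form checks).
#' @return list of [accel_trace()] objects, one per bird.
#' @export
simulate_accel <- function(plan, birds, truth, seed = 1L, duration_s = 60,
                           sample_rate_hz = 200, noise_sd = 0,
                           spacing_m = NULL,
                           waveform = c("two_segment", "sinusoid")) {
  plan <- as.list(plan)
  waveform <- match.arg(waveform)
  set.seed(as.integer(seed) + 29L)
  is_pair <- identical(plan$condition, "pair")
  if (is.null(spacing_m)) spacing_m <- if (is_pair) truth$spacing_mean_m else 0
  ids <- if (is_pair) c(plan$bird1, plan$bird2) else plan$bird1
  cov_shift <- covariate_shift(truth, plan)
  tt <- seq(0, duration_s, by = 1 / sample_rate_hz)
  out <- list()
  for (b in seq_along(ids)) {
    me <- birds[birds$bird_id == ids[b], ]
    if (nrow(me) != 1) stop("bird ", ids[b], " not found in the registry")
    mu_i <- me$solo_freq_hz
    if (is_pair) {
      other <- birds[birds$bird_id == ids[if (b == 1) 2 else 1], ]
      d_t <- abs(me$tarsus_mm - other$tarsus_mm)
      omega <- stats::plogis(truth$eta1 + truth$eta_s * d_t)
      f <- truth$delta0_hz + truth$delta1_hz_per_mm * d_t +
        truth$spacing_slope_hz_per_m * spacing_m +
        omega * mu_i + (1 - omega) * other$solo_freq_hz
    } else {
      f <- mu_i
    }
    f <- f + cov_shift + stats::rnorm(1, 0, truth$residual_sd_hz)
    if (f <= 0) stop("generated wingbeat frequency is non-positive")
    z <- if (waveform == "sinusoid") {
      (truth$pp_accel_g / 2) * cos(2 * pi * f * tt)
    } else {
      down_s <- (1 - truth$upstroke_frac) / mu_i
      two_segment_wave(tt, f, truth$pp_accel_g, down_s)
    }
    z <- z + 1
    if (noise_sd > 0) z <- z + stats::rnorm(length(tt), 0, noise_sd)
    out[[b]] <- accel_trace(tt, z,
                            ax_g = stats::rnorm(length(tt), 0, 0.05),
                            ay_g = stats::rnorm(length(tt), 0, 0.05),
                            sample_rate_hz = sample_rate_hz,
                            flight_id = plan$flight_id, bird_id = ids[b])
  }
  out
}

#' Generate flight-median summaries directly from the generative model
#'
#' Bypasses trace/track simulation and draws the row unit of the
#' hierarchical model straight from the flight-median equation: solo
#' rows \eqn{N(\mu_i + \gamma X, \sigma)}, paired rows
#' \eqn{N(\delta_0 + \delta_1|T_i - T_j| + \omega_i \mu_i +
#' (1-\omega_i)\mu_j + \gamma X, \sigma)}. Partners are drawn uniformly
#' from the other birds per paired flight. Used by the model-recovery
#' worlds, where simulating every 200 Hz trace would add nothing.
#'
#' @param birds registry from [make_birds()].
#' @param truth a [truth_record()].
#' @param n_solo,n_pair flights per bird in each condition.
#' @param seed integer seed.
#' @param covariates logical; draw weather/airspeed covariates and apply
#'   `truth$covariate_effects` (default TRUE).
#' @return data.frame of flight summaries: `flight_id`, `bird_id`,
#'   `partner_id`, `is_pair`, `tarsus_diff_mm`, `freq_hz`,
#'   `spacing_median_m`, plus covariate columns.
#' @export
simulate_flight_summaries <- function(birds, truth, n_solo = 12,
                                      n_pair = 12, seed = 1L,
                                      covariates = TRUE) {
  set.seed(as.integer(seed) + 7L)
  n <- nrow(birds)
  rows <- list(); r <- 0L
  for (b in seq_len(n)) {
    for (k in seq_len(n_solo + n_pair)) {
      r <- r + 1L
      is_pair <- k > n_solo
      partner <- NA_character_; d_t <- 0; mu_j <- 0; omega <- 1
      if (is_pair) {
        j <- sample(setdiff(seq_len(n), b), 1)
        partner <- birds$bird_id[j]
        d_t <- abs(birds$tarsus_mm[b] - birds$tarsus_mm[j])
        mu_j <- birds$solo_freq_hz[j]
        omega <- stats::plogis(truth$eta1 + truth$eta_s * d_t)
      }
      covs <- if (covariates) {
        list(airspeed = stats::rnorm(1, 19.1 + is_pair * 0.63, 0.8),
             wind_support = stats::rnorm(1, 0, 2),
             crosswind = abs(stats::rnorm(1, 0, 1.5)),
             temp_c = stats::runif(1, 12, 25),
             humidity_pct = stats::runif(1, 40, 90),
             rho_air = stats::rnorm(1, 1.21, 0.01))
      } else list()
      m <- if (is_pair) {
        truth$delta0_hz + truth$delta1_hz_per_mm * d_t +
          omega * birds$solo_freq_hz[b] + (1 - omega) * mu_j
      } else {
        birds$solo_freq_hz[b]
      }
      m <- m + covariate_shift(truth, covs)
      base <- data.frame(
        flight_id = sprintf("M%05d", r),
        bird_id = birds$bird_id[b],
        partner_id = partner,
        is_pair = as.integer(is_pair),
        tarsus_diff_mm = d_t,
        freq_hz = stats::rnorm(1, m, truth$residual_sd_hz),
        spacing_median_m = if (is_pair) {
          max(0.5, stats::rnorm(1, truth$spacing_mean_m, 4))
        } else NA_real_)
      rows[[r]] <- if (length(covs)) cbind(base, covs) else base
    }
  }
  do.call(rbind, rows)
}

#' Generate a wingbeat-level sample for the spacing model
#'
#' Draws `beats_per_flight` wingbeats for each of `n_pair` paired and
#' `n_solo` solo flights. Each flight gets a Gaussian flight-level
#' effect (SD `flight_effect_sd`); paired wingbeats get a spacing drawn
#' uniformly on [0, 50] m and a frequency shift of the pairing intercept
#' plus slope times spacing.
#'
#' @param truth a [truth_record()]; `delta0_hz` is interpreted here as
#'   the pairing effect at 0 m spacing and `spacing_slope_hz_per_m` as
#'   the per-metre slope.
#' @param n_pair,n_solo number of flights per condition.
#' @param beats_per_flight sampled wingbeats per flight (default 100).
#' @param base_freq_hz solo baseline frequency (default 5.48).
#' @param flight_effect_sd SD of the per-flight effect, Hz.
#' @param beat_sd_hz within-flight wingbeat-to-wingbeat SD, Hz.
#' @param seed integer seed.
#' @return data.frame with `flight_id`, `is_pair`, `spacing_m`,
#'   `freq_hz`.
#' @export
simulate_wingbeat_sample <- function(truth, n_pair = 50, n_solo = 50,
                                     beats_per_flight = 100,
                                     base_freq_hz = 5.48,
                                     flight_effect_sd = 0.1,
                                     beat_sd_hz = 0.25, seed = 1L) {
  set.seed(as.integer(seed) + 11L)
  nf <- n_pair + n_solo
  is_pair <- rep(c(1L, 0L), c(n_pair, n_solo))
  b_f <- stats::rnorm(nf, 0, flight_effect_sd)
  out <- lapply(seq_len(nf), function(f) {
    sp <- if (is_pair[f] == 1L) {
      stats::runif(beats_per_flight, 0, 50)
    } else rep(NA_real_, beats_per_flight)
    m <- base_freq_hz + b_f[f] + if (is_pair[f] == 1L) {
      truth$delta0_hz + truth$spacing_slope_hz_per_m * sp
    } else 0
    data.frame(flight_id = sprintf("W%04d", f), is_pair = is_pair[f],
               spacing_m = sp,
               freq_hz = stats::rnorm(beats_per_flight, m, beat_sd_hz))
  })
  do.call(rbind, out)
}

#' Write a synthetic dataset to CSV files plus a truth record
#'
#' Emits `birds.csv`, `flights.csv`, `gps.csv`, `accel.csv`,
#' `weather.csv` and `truth.json` with fixed schemas, checking id
#' consistency first. All numeric columns are written in full precision
#' so the files round-trip losslessly through [read_dataset()].
#'
#' @param plans flight plans ([make_flight_plans()]).
#' @param tracks list of [gps_track()] objects.
#' @param traces list of [accel_trace()] objects.
#' @param weather data.frame in the `weather.csv` schema (`t_epoch`,
#'   `wind_speed_ms`, `wind_dir_deg`, `temp_c`, `humidity_pct`,
#'   `pressure_hpa`).
#' @param registry bird registry ([make_birds()]).
#' @param out_dir output directory (created if needed).
#' @param truth a [truth_record()].
#' @return invisibly, the vector of files written.
#' @export
emit_dataset <- function(plans, tracks, traces, weather, registry,
                         out_dir, truth) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  plan_birds <- stats::na.omit(unique(c(plans$bird1, plans$bird2)))
  bad <- setdiff(plan_birds, registry$bird_id)
  track_flights <- unique(vapply(tracks, attr, "", "flight_id"))
  bad_f <- setdiff(track_flights, plans$flight_id)
  trace_flights <- unique(vapply(traces, attr, "", "flight_id"))
  bad_f <- c(bad_f, setdiff(trace_flights, plans$flight_id))
  if (length(bad) || length(bad_f)) {
    stop("id mismatch: unknown ids ",
         paste(unique(c(bad, bad_f)), collapse = ", "))
  }
  stack <- function(objs, cols) {
    if (length(objs) == 0) {
      return(stats::setNames(
        data.frame(matrix(nrow = 0, ncol = length(cols) + 2)),
        c("flight_id", "bird_id", cols)))
    }
    data.table::rbindlist(lapply(objs, function(o) {
      cbind(data.frame(flight_id = attr(o, "flight_id"),
                       bird_id = attr(o, "bird_id")),
            as.data.frame(o)[, cols, drop = FALSE])
    }))
  }
  gps <- stack(tracks, c("t_s", "lat_deg", "lon_deg"))
  accel <- stack(traces, c("t_s", "ax_g", "ay_g", "az_g"))
  flights <- data.frame(flight_id = plans$flight_id, phase = plans$phase,
                        condition = plans$condition, pair_id = plans$pair_id,
                        bird_ids = ifelse(is.na(plans$bird2), plans$bird1,
                                          paste(plans$bird1, plans$bird2,
                                                sep = ";")),
                        release_epoch = plans$release_epoch)
  paths <- file.path(out_dir, c("birds.csv", "flights.csv", "gps.csv",
                                "accel.csv", "weather.csv", "truth.json"))
  data.table::fwrite(registry, paths[1])
  data.table::fwrite(flights, paths[2])
  data.table::fwrite(gps, paths[3])
  data.table::fwrite(accel, paths[4])
  data.table::fwrite(weather, paths[5])
  tr <- unclass(truth)
  tr$covariate_effects <- as.list(tr$covariate_effects)
  jsonlite::write_json(tr, paths[6], auto_unbox = TRUE, digits = NA)
  invisible(paths)
}

#' Read a dataset written by [emit_dataset()]
#'
#' @param dir directory containing the CSV files.
#' @return list with `birds`, `flights`, `gps`, `accel`, `weather`
#'   data.frames and `truth` (a [truth_record()]).
#' @export
read_dataset <- function(dir) {
  rd <- function(f) as.data.frame(data.table::fread(file.path(dir, f)))
  tr <- jsonlite::read_json(file.path(dir, "truth.json"),
                            simplifyVector = TRUE)
  ce <- unlist(tr$covariate_effects)
  tr <- tr[setdiff(names(tr), c("covariate_effects", "seed"))]
  truth <- do.call(truth_record,
                   c(tr, list(covariate_effects = ce, seed = 1L)))
  list(birds = rd("birds.csv"), flights = rd("flights.csv"),
       gps = rd("gps.csv"), accel = rd("accel.csv"),
       weather = rd("weather.csv"), truth = truth)
}

#' Per-minute weather table for a set of flight plans
#'
#' Expands each plan's constant within-flight weather into one row per
#' minute covering the release window.
#'
#' @param plans flight plans ([make_flight_plans()]).
#' @param duration_s covered duration per flight, seconds.
#' @return data.frame in the `weather.csv` schema.
#' @export
weather_table <- function(plans, duration_s = 600) {
  if (nrow(plans) == 0) {
    return(data.frame(t_epoch = numeric(0), wind_speed_ms = numeric(0),
                      wind_dir_deg = numeric(0), temp_c = numeric(0),
                      humidity_pct = numeric(0), pressure_hpa = numeric(0)))
  }
  out <- lapply(seq_len(nrow(plans)), function(i) {
    mins <- seq(0, duration_s, by = 60)
    data.frame(t_epoch = plans$release_epoch[i] + mins,
               wind_speed_ms = plans$wind_speed_ms[i],
               wind_dir_deg = plans$wind_dir_deg[i],
               temp_c = plans$temp_c[i],
               humidity_pct = plans$humidity_pct[i],
               pressure_hpa = plans$pressure_hpa[i])
  })
  do.call(rbind, out)
}
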