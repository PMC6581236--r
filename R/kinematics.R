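# Per-wingbeat kinematics from tri-axial accelerometry.
#
# Processing chain for a dorsal (back-mounted) logger:
#   smooth (3-sample running mean) -> remove_gravity (long running mean)
#   -> detect_wingbeats (acceleration maxima) -> stroke_phases,
#   pp_displacement.
# Head-mounted traces swap the gravity step for a 4th-order zero-phase
# Butterworth high-pass at 1 Hz and a 5-sample smoothing window.

#' Construct an accelerometer trace
#'
#' @param t_s sample times, seconds, strictly increasing (nominally
#'   uniform).
#' @param ax_g,ay_g,az_g acceleration per axis in units of g. `az_g` is
#'   the dorsal/vertical channel used for wingbeat analysis.
#' @param sample_rate_hz nominal sampling rate, Hz.
#' @param mount `"dorsal"` or `"head"`.
#' @param flight_id,bird_id optional identifiers, kept as attributes.
#' @return data.frame of class `accel_trace`.
#' @export
accel_trace <- function(t_s, az_g, ax_g = NULL, ay_g = NULL,
                        sample_rate_hz = 200,
                        mount = c("dorsal", "head"),
                        flight_id = NA, bird_id = NA) {
  mount <- match.arg(mount)
  if (sample_rate_hz <= 0) stop("sample_rate_hz must be positive")
  if (any(diff(t_s) <= 0)) stop("t_s must be strictly increasing")
  if (any(!is.finite(az_g))) stop("acceleration values must be finite")
  n <- length(t_s)
  if (is.null(ax_g)) ax_g <- numeric(n)
  if (is.null(ay_g)) ay_g <- numeric(n)
  structure(data.frame(t_s = t_s, ax_g = ax_g, ay_g = ay_g, az_g = az_g),
            sample_rate_hz = sample_rate_hz, mount = mount,
            flight_id = flight_id, bird_id = bird_id,
            class = c("accel_trace", "data.frame"))
}

restamp <- function(trace, ax, ay, az) {
  out <- trace
  out$ax_g <- ax; out$ay_g <- ay; out$az_g <- az
  out
}

#' Smooth a trace with a centred running mean
#'
#' Each channel is replaced by its centred moving average; near the
#' edges the window shrinks symmetrically, so the length is preserved
#' and affine signals pass unchanged.
#'
#' @param trace an [accel_trace()].
#' @param window window length in samples; odd, >= 1 (1 = identity).
#'   The conventional choices are 3 samples for a 200 Hz dorsal logger
#'   and 5 samples for a 60 Hz head-mounted one.
#' @return the smoothed trace.
#' @export
smooth_trace <- function(trace, window = 3) {
  restamp(trace,
          running_mean(trace$ax_g, window),
          running_mean(trace$ay_g, window),
          running_mean(trace$az_g, window))
}

#' Remove static (gravitational) acceleration
#'
#' Subtracts a long centred running mean from each channel, leaving the
#' dynamic acceleration. The window should span many wingbeat cycles;
#' the default 2.75 s covers about 15 cycles at a typical 5.5 Hz
#' wingbeat frequency.
#'
#' @param trace an [accel_trace()].
#' @param window_s running-mean length, seconds (> 0).
#' @return the dynamic trace (channels in g, zero-mean at long scales).
#' @export
remove_gravity <- function(trace, window_s = 2.75) {
  if (window_s <= 0) stop("window_s must be positive")
  fs <- attr(trace, "sample_rate_hz")
  w <- round(window_s * fs)
  if (w %% 2 == 0) w <- w + 1
  if (w > nrow(trace)) stop("gravity window longer than the trace")
  restamp(trace,
          trace$ax_g - running_mean(trace$ax_g, w),
          trace$ay_g - running_mean(trace$ay_g, w),
          trace$az_g - running_mean(trace$az_g, w))
}

#' Zero-phase Butterworth high-pass filter
#'
#' Applies a digital Butterworth high-pass forward and backward
#' (zero-phase, squared magnitude response) to every channel. Used in
#' place of [remove_gravity()] for head-mounted loggers.
#'
#' @param trace an [accel_trace()].
#' @param order filter order (default 4).
#' @param cutoff_hz cutoff frequency, Hz; must be below Nyquist
#'   (default 1).
#' @return the filtered trace.
#' @export
butter_highpass <- function(trace, order = 4, cutoff_hz = 1) {
  fs <- attr(trace, "sample_rate_hz")
  if (cutoff_hz >= fs / 2) stop("cutoff_hz must be below the Nyquist frequency")
  d <- butter_hp_design(order, cutoff_hz, fs)
  restamp(trace,
          filt_filt(d$b, d$a, trace$ax_g),
          filt_filt(d$b, d$a, trace$ay_g),
          filt_filt(d$b, d$a, trace$az_g))
}

# local maxima of x with minimum separation (samples) and minimum
# prominence; returns indices, greedily keeping the most prominent
find_peaks <- function(x, min_sep, min_prom) {
  n <- length(x)
  d <- diff(x)
  cand <- which(d[-length(d)] > 0 & d[-1] <= 0) + 1
  if (length(cand) == 0) return(integer(0))
  prom <- vapply(cand, function(i) {
    h <- x[i]
    lmin <- h
    j <- i - 1
    while (j >= 1 && x[j] <= h) { if (x[j] < lmin) lmin <- x[j]; j <- j - 1 }
    if (j < 1) lmin <- min(x[1:i])
    rmin <- h
    j <- i + 1
    while (j <= n && x[j] <= h) { if (x[j] < rmin) rmin <- x[j]; j <- j + 1 }
    if (j > n) rmin <- min(x[i:n])
    h - max(lmin, rmin)
  }, numeric(1))
  keep <- cand[prom >= min_prom]
  if (length(keep) == 0) return(integer(0))
  ord <- keep[order(x[keep], decreasing = TRUE)]
  sel <- logical(0)
  chosen <- integer(0)
  for (i in ord) {
    if (all(abs(chosen - i) >= min_sep)) chosen <- c(chosen, i)
  }
  sort(chosen)
}

# Sub-sample refinement of an extremum by a shared-apex piecewise
# polynomial: y ~ h + a_s (t - t0)^2 + b_s (t - t0)^4 with separate
# (a, b) on each side of the apex, fitted by least squares to the 7
# samples around the discrete extremum over a fine grid of candidate
# apex times t0 (the RSS minimum is then interpolated). Any C1 signal
# looks like this locally, including waveforms whose curvature differs
# on the two sides of the peak (unequal stroke-phase durations), where
# a plain 3-point parabola is biased by several ms. Returns a closure
# so the per-t0 projection matrices are built once per trace.
make_apex_refiner <- function(half_width = 3L, factor = 32L) {
  tj <- seq(-half_width, half_width)
  t0s <- seq(-1, 1, by = 1 / factor)
  pre <- lapply(t0s, function(t0) {
    d <- tj - t0
    B <- cbind(1, d^2 * (d < 0), d^2 * (d >= 0),
               d^4 * (d < 0), d^4 * (d >= 0))
    P <- solve(crossprod(B), t(B))    # coefficient projector
    list(P = P, H = B %*% P)
  })
  function(x, i) {
    n <- length(x)
    if (i <= half_width || i > n - half_width) {
      # fallback: 3-point parabola at the edge
      if (i <= 1 || i >= n) return(list(dt = 0, dy = 0))
      den <- x[i - 1] - 2 * x[i] + x[i + 1]
      if (den == 0) return(list(dt = 0, dy = 0))
      dt <- max(-0.5, min(0.5, 0.5 * (x[i - 1] - x[i + 1]) / den))
      return(list(dt = dt, dy = -0.25 * (x[i - 1] - x[i + 1]) * dt))
    }
    y <- x[(i - half_width):(i + half_width)]
    rss <- vapply(pre, function(p) sum((y - p$H %*% y)^2), numeric(1))
    k <- which.min(rss)
    dt <- t0s[k]
    # de-quantise: parabolic interpolation of the RSS minimum over t0
    if (k > 1 && k < length(rss)) {
      den <- rss[k - 1] - 2 * rss[k] + rss[k + 1]
      if (den > 0) {
        dt <- dt + max(-0.5, min(0.5, 0.5 * (rss[k - 1] - rss[k + 1]) /
                                   den)) / factor
      }
    }
    h <- (pre[[k]]$P %*% y)[1]
    list(dt = dt, dy = h - x[i])
  }
}

#' Segment a dynamic trace into wingbeats
#'
#' Wingbeats are delimited by successive maxima of the dynamic dorsal
#' (vertical) acceleration. Maxima are found by local-extremum search
#' with a minimum peak separation (default 55 ms) and a minimum
#' prominence expressed as a fraction (default 0.3) of the channel's
#' inter-quartile range; extremum times are refined to sub-sample
#' precision by parabolic interpolation, and the minimum within each
#' beat is located the same way (earliest sample on ties).
#'
#' @param trace a gravity-removed (or high-passed) [accel_trace()].
#' @param min_sep_s minimum separation between retained maxima, seconds.
#' @param prominence_frac prominence threshold as a fraction of the IQR.
#' @return data.frame of class `wingbeat_table` with one row per beat:
#'   `start_s`, `end_s`, `min_s` (time of the in-beat minimum),
#'   `freq_hz`, `pp_accel_g`. Empty (with a warning) if fewer than 3
#'   maxima are found.
#' @export
detect_wingbeats <- function(trace, min_sep_s = 0.055,
                             prominence_frac = 0.3) {
  x <- trace$az_g
  fs <- attr(trace, "sample_rate_hz")
  prom <- prominence_frac * stats::IQR(x)
  pk <- find_peaks(x, min_sep = min_sep_s * fs, min_prom = prom)
  empty <- data.frame(start_s = numeric(0), end_s = numeric(0),
                      min_s = numeric(0), freq_hz = numeric(0),
                      pp_accel_g = numeric(0))
  class(empty) <- c("wingbeat_table", "data.frame")
  if (length(pk) < 3) {
    warning("fewer than 3 acceleration maxima detected; returning empty table")
    return(empty)
  }
  refine <- make_apex_refiner()
  ref <- lapply(pk, function(i) refine(x, i))
  tpk <- trace$t_s[pk] + vapply(ref, `[[`, numeric(1), "dt") / fs
  hpk <- x[pk] + vapply(ref, `[[`, numeric(1), "dy")

  nb <- length(pk) - 1
  min_s <- numeric(nb)
  min_h <- numeric(nb)
  for (k in seq_len(nb)) {
    seg <- pk[k]:pk[k + 1]
    im <- seg[which.min(x[seg])]   # which.min takes the earliest on ties
    r <- refine(x, im)
    min_s[k] <- trace$t_s[im] + r$dt / fs
    min_h[k] <- x[im] + r$dy
  }
  period <- diff(tpk)
  out <- data.frame(start_s = tpk[-length(tpk)], end_s = tpk[-1],
                    min_s = min_s, freq_hz = 1 / period,
                    pp_accel_g = hpk[-length(hpk)] - min_h)
  class(out) <- c("wingbeat_table", "data.frame")
  out
}

#' Stroke-phase durations per wingbeat
#'
#' The downstroke phase runs from the acceleration maximum (peak
#' downstroke force) to the following minimum (lower reversal point);
#' the upstroke phase from that minimum to the next maximum. The two
#' durations sum to the wingbeat period exactly.
#'
#' @param wingbeats a `wingbeat_table` from [detect_wingbeats()].
#' @return the table with `down_ms` and `up_ms` columns added.
#' @export
stroke_phases <- function(wingbeats) {
  wingbeats$down_ms <- (wingbeats$min_s - wingbeats$start_s) * 1000
  wingbeats$up_ms <- (wingbeats$end_s - wingbeats$min_s) * 1000
  wingbeats
}

cumtrapz <- function(t, x) {
  n <- length(x)
  c(0, cumsum(diff(t) * (x[-1] + x[-n]) / 2))
}

#' Peak-to-peak oscillatory displacement per wingbeat
#'
#' Double trapezoidal integration of the dynamic vertical acceleration
#' (converted g to m/s^2 with 9.80665), performed independently within
#' each beat to control integration drift: the velocity is de-meaned
#' over the beat and the displacement linearly detrended before taking
#' max minus min. For a pure sinusoid of amplitude a this recovers the
#' closed form a / (2 pi f)^2.
#'
#' @param trace the dynamic [accel_trace()] the beats were detected on.
#' @param wingbeats a `wingbeat_table`.
#' @return the table with a `pp_disp_mm` column added (NA for beats
#'   spanning fewer than 3 samples).
#' @export
pp_displacement <- function(trace, wingbeats) {
  disp <- vapply(seq_len(nrow(wingbeats)), function(k) {
    sel <- trace$t_s >= wingbeats$start_s[k] & trace$t_s <= wingbeats$end_s[k]
    if (sum(sel) < 3) return(NA_real_)
    tt <- trace$t_s[sel]
    a <- trace$az_g[sel] * 9.80665
    v <- cumtrapz(tt, a)
    v <- v - mean(v)
    d <- cumtrapz(tt, v)
    tc <- tt - mean(tt)
    d <- d - mean(d) - (sum(tc * d) / sum(tc^2)) * tc
    (max(d) - min(d)) * 1000
  }, numeric(1))
  wingbeats$pp_disp_mm <- disp
  wingbeats
}

#' Full per-wingbeat kinematics for one trace
#'
#' Convenience wrapper running the whole chain. For `mount = "dorsal"`:
#' 3-sample smoothing and running-mean gravity removal; for
#' `mount = "head"`: 5-sample smoothing and a 4th-order 1 Hz zero-phase
#' Butterworth high-pass.
#'
#' @param trace a raw [accel_trace()].
#' @param smooth_window,gravity_window_s,butter_order,butter_cutoff_hz
#'   processing constants; defaults depend on the mount.
#' @return a `wingbeat_table` with frequency, peak-to-peak acceleration,
#'   displacement and stroke-phase durations.
#' @export
wingbeat_metrics <- function(trace, smooth_window = NULL,
                             gravity_window_s = 2.75,
                             butter_order = 4, butter_cutoff_hz = 1) {
  head_mount <- identical(attr(trace, "mount"), "head")
  if (is.null(smooth_window)) smooth_window <- if (head_mount) 5 else 3
  dyn <- smooth_trace(trace, smooth_window)
  dyn <- if (head_mount) {
    butter_highpass(dyn, butter_order, butter_cutoff_hz)
  } else {
    remove_gravity(dyn, gravity_window_s)
  }
  wb <- detect_wingbeats(dyn)
  if (nrow(wb) == 0) return(wb)
  pp_displacement(dyn, stroke_phases(wb))
}
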