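# Shared fixtures: constructed waveforms and small tracks, built in code.

LOFT <- list(lat = 51 + 46 / 60 + 58.2 / 3600,
             lon = -(1 + 19 / 60 + 2.7 / 3600))
RELEASE <- list(lat = 51 + 47 / 60 + 48.1 / 3600,
                lon = -(1 + 25 / 60 + 3.3 / 3600))

# dynamic (zero-mean) two-segment wingbeat waveform as an accel_trace
two_seg_trace <- function(down_s, up_s, pp_g = 2.5, duration_s = 60,
                          fs = 200, static_g = 0) {
  tt <- seq(0, duration_s, by = 1 / fs)
  f <- 1 / (down_s + up_s)
  period <- down_s + up_s
  ph <- tt %% period
  a <- pp_g / 2
  z <- ifelse(ph < down_s, a * cos(pi * ph / down_s),
              -a * cos(pi * (ph - down_s) / up_s))
  accel_trace(tt, z + static_g, sample_rate_hz = fs)
}

sinusoid_trace <- function(freq_hz, pp_g = 2.5, duration_s = 60, fs = 200,
                           static_g = 0, mount = "dorsal") {
  tt <- seq(0, duration_s, by = 1 / fs)
  accel_trace(tt, static_g + (pp_g / 2) * cos(2 * pi * freq_hz * tt),
              sample_rate_hz = fs, mount = mount)
}

# straight track from `start` along `bearing` at `speed` for `n` fixes
straight_track <- function(start, bearing, speed = 19, n = 100, dt = 0.2) {
  lat <- numeric(n); lon <- numeric(n)
  lat[1] <- start$lat; lon[1] <- start$lon
  for (i in seq_len(n - 1)) {
    p <- destination_point(lat[i], lon[i], bearing, speed * dt)
    lat[i + 1] <- p$lat; lon[i + 1] <- p$lon
  }
  gps_track(seq(0, by = dt, length.out = n), lat, lon)
}

# track built from an explicit per-step heading sequence
heading_track <- function(start, headings, step_m = 4, dt = 0.2) {
  n <- length(headings) + 1
  lat <- numeric(n); lon <- numeric(n)
  lat[1] <- start$lat; lon[1] <- start$lon
  for (i in seq_along(headings)) {
    p <- destination_point(lat[i], lon[i], headings[i], step_m)
    lat[i + 1] <- p$lat; lon[i + 1] <- p$lon
  }
  gps_track(seq(0, by = dt, length.out = n), lat, lon)
}
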