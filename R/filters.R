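# Minimal signal-processing primitives: centred moving average with
# shrinking edges, IIR filtering, and a digital Butterworth high-pass
# designed by bilinear transform of the analog prototype. Hand-written
# because no DSP package is assumed; verified against the analog
# magnitude response at pre-warped frequencies.

# centred running mean; at the edges the half-width shrinks symmetrically
# so the window stays centred (this preserves affine signals everywhere)
running_mean <- function(x, window) {
  if (window < 1 || window %% 2 == 0) stop("window must be odd and >= 1")
  n <- length(x)
  if (window > n) stop("window longer than the signal")
  if (window == 1) return(x)
  h <- (window - 1) / 2
  idx <- seq_len(n)
  k <- pmin(h, idx - 1, n - idx)
  cs <- c(0, cumsum(x))
  (cs[idx + k + 1] - cs[idx - k]) / (2 * k + 1)
}

# polynomial coefficients (highest power first) from roots
poly_from_roots <- function(r) {
  p <- 1
  for (root in r) p <- c(p, 0) - c(0, p * root)
  p
}

# digital Butterworth high-pass, returns list(b, a) in z^-1 form
butter_hp_design <- function(order, cutoff_hz, fs) {
  if (cutoff_hz <= 0 || cutoff_hz >= fs / 2) {
    stop("cutoff must lie in (0, Nyquist)")
  }
  k <- seq_len(order)
  # analog low-pass prototype poles on the unit circle, left half-plane
  p_lp <- exp(1i * pi * (2 * k + order - 1) / (2 * order))
  wc <- 2 * fs * tan(pi * cutoff_hz / fs)   # pre-warped cutoff, rad/s
  p_hp <- wc / p_lp                          # LP -> HP transform
  # bilinear transform s -> 2 fs (z-1)/(z+1)
  pz <- (2 * fs + p_hp) / (2 * fs - p_hp)
  a <- Re(poly_from_roots(pz))
  b <- poly_from_roots(rep(1, order))        # n zeros at z = 1 (DC)
  # unit gain at Nyquist (z = -1)
  zpow <- (-1)^(0:order)
  gain <- sum(a * zpow) / sum(b * zpow)
  list(b = b * gain, a = a)
}

# direct-form IIR filter, zero initial conditions
iir_filter <- function(b, a, x) {
  nb <- length(b)
  xp <- c(rep(0, nb - 1), x)
  num <- stats::filter(xp, b, method = "convolution", sides = 1)
  num <- as.numeric(num)[nb - 1 + seq_along(x)]
  if (length(a) > 1) {
    num <- as.numeric(stats::filter(num, -a[-1], method = "recursive"))
  }
  num
}

# zero-phase forward-backward filtering with odd-reflection padding long
# enough for the start-up transient to die out
filt_filt <- function(b, a, x, padlen = NULL) {
  n <- length(x)
  if (is.null(padlen)) padlen <- min(n - 1, max(3 * length(a), 500))
  ix <- seq(padlen + 1, 2)
  jx <- seq(n - 1, n - padlen)
  xp <- c(2 * x[1] - x[ix], x, 2 * x[n] - x[jx])
  y <- iir_filter(b, a, xp)
  y <- rev(iir_filter(b, a, rev(y)))
  y[padlen + seq_len(n)]
}

# |H(e^{i 2 pi f / fs})| of a digital filter, for tests/diagnostics
digital_gain <- function(b, a, freq_hz, fs) {
  w <- 2 * pi * freq_hz / fs
  z <- exp(-1i * w)
  num <- vapply(z, function(zz) sum(b * zz^(0:(length(b) - 1))), complex(1))
  den <- vapply(z, function(zz) sum(a * zz^(0:(length(a) - 1))), complex(1))
  Mod(num / den)
}
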