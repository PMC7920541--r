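# Internal numerical helpers shared across modules.

#' Draw from a von Mises distribution
#'
#' Best-Fisher (1979) rejection sampler. Used for per-trial phase jitter of
#' coupled channel pairs; exposed because the Monte-Carlo oracles in the test
#' suite need the same primitive.
#'
#' @param n number of draws.
#' @param mu mean direction (radians).
#' @param kappa concentration parameter (>= 0); 0 gives a uniform angle.
#' @return numeric vector of angles in (-pi, pi].
#' @export
rvonmises <- function(n, mu = 0, kappa = 0) {
  stopifnot(kappa >= 0, n >= 0)
  if (n == 0L) return(numeric(0))
  if (kappa == 0) return(stats::runif(n, -pi, pi))
  if (!is.finite(kappa)) return(rep(wrap_angle(mu), n))
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  out <- numeric(n)
  i <- 1L
  while (i <= n) {
    u <- stats::runif(3)
    z <- cos(pi * u[1])
    f <- (1 + r * z) / (r + z)
    c0 <- kappa * (r - f)
    if (c0 * (2 - c0) - u[2] > 0 || log(c0 / u[2]) + 1 - c0 >= 0) {
      out[i] <- sign(u[3] - 0.5) * acos(f)
      i <- i + 1L
    }
  }
  wrap_angle(out + mu)
}

# Wrap angles into (-pi, pi].
wrap_angle <- function(x) {
  y <- (x + pi) %% (2 * pi) - pi
  y[y == -pi] <- pi
  y
}

# Map the user-facing coupling strength kappa in [0, 1] to a von Mises
# concentration: 0 -> 0 (no coupling), 1 -> Inf (rigid phase lag). Monotone.
kappa_to_concentration <- function(kappa) {
  stopifnot(all(kappa >= 0 & kappa <= 1))
  ifelse(kappa >= 1, Inf, 2 * kappa / (1 - kappa))
}

#' Generate 1/f ("pink") Gaussian noise
#'
#' Spectral-shaping generator: white Gaussian noise is filtered in the
#' frequency domain so the power spectrum falls as 1/f^exponent, then scaled
#' to the requested standard deviation.
#'
#' @param n number of samples.
#' @param fs sampling rate in Hz.
#' @param exponent spectral slope of the power spectrum (1 = pink noise).
#' @param sd target standard deviation of the output.
#' @return numeric vector of length `n`.
#' @export
one_over_f_noise <- function(n, fs = 1000, exponent = 1, sd = 1) {
  stopifnot(n >= 2, fs > 0, exponent >= 0, sd >= 0)
  nfft <- stats::nextn(n, c(2, 3, 5))
  # draw the spectrum directly: complex white Gaussian coefficients shaped
  # by f^(-exponent/2); the real part of one inverse FFT is Gaussian 1/f
  # noise (a forward transform of white noise is not needed)
  f <- seq(0, fs - fs / nfft, length.out = nfft)
  f[f > fs / 2] <- fs - f[f > fs / 2]   # mirror for negative frequencies
  gain <- rep(0, nfft)
  nz <- f > 0
  gain[nz] <- f[nz]^(-exponent / 2)     # amplitude scaling = sqrt(power)
  spec <- complex(real = stats::rnorm(nfft), imaginary = stats::rnorm(nfft))
  x <- Re(stats::fft(spec * gain, inverse = TRUE)) / nfft
  x <- x[seq_len(n)]
  x <- x - mean(x)
  s <- stats::sd(x)
  if (s > 0 && sd > 0) x <- x * (sd / s) else x[] <- 0
  x
}

# Hann taper over a window given in samples (length n).
hann_taper <- function(n) {
  if (n == 1L) return(1)
  0.5 - 0.5 * cos(2 * pi * seq(0, n - 1) / (n - 1))
}

# Tukey (tapered cosine) envelope: flat at 1 except for cosine ramps of
# fraction r/2 at each end. Planted effects use this so that "sustained"
# activity really is sustained across its window (a Hann envelope would put
# most of the window at half amplitude) while still switching on/off
# smoothly.
tukey_taper <- function(n, r = 0.2) {
  if (n == 1L) return(1)
  x <- seq(0, 1, length.out = n)
  env <- rep(1, n)
  lo <- x < r / 2
  hi <- x > 1 - r / 2
  env[lo] <- 0.5 * (1 + cos(pi * (2 * x[lo] / r - 1)))
  env[hi] <- 0.5 * (1 + cos(pi * (2 * (x[hi] - 1) / r + 1)))
  env
}

# Spearman rank correlation (thin wrapper so intent reads at call sites).
spearman <- function(x, y) stats::cor(x, y, method = "spearman")
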