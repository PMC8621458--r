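## Shared helpers: seed derivation, validation, periodograms.

## Deterministic per-task child seeds below 2^31, Lehmer-style mix of the
## master seed and a task index.
derive_seed <- function(seed, index) {
  m <- 2147483647
  s <- (as.double(seed) %% m) + 1
  for (k in c(index + 1, 7919)) {
    s <- (s * 48271 + k) %% m
  }
  as.integer(s)
}

stopifnot_scalar_number <- function(x, name, min = -Inf, max = Inf) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x)) {
    abort(sprintf("`%s` must be a single non-missing number.", name))
  }
  if (x < min || x > max) {
    abort(sprintf("`%s` must be in [%s, %s], got %s.", name, min, max, x))
  }
  invisible(x)
}

## One-sided periodogram of a real window, DC excluded.
## Returns tibble(freq, power); sum(power) over all bins equals the mean
## squared signal minus the DC (mean^2) term, so a unit-amplitude sinusoid at
## a bin frequency contributes power 1/2 at that bin (Parseval).
periodogram <- function(x, fs) {
  n <- length(x)
  X <- fft(x)
  half <- floor(n / 2)
  k <- seq_len(half)                          # bins 1 .. n/2
  p <- 2 * Mod(X[k + 1L])^2 / n^2
  if (n %% 2L == 0L) p[half] <- p[half] / 2   # Nyquist bin is not doubled
  tibble(freq = k * fs / n, power = p)
}

## Sum of periodogram power over band bins with low <= f <= high (inclusive).
band_power_from_pgram <- function(pg, low, high) {
  sel <- pg$freq >= low - 1e-9 & pg$freq <= high + 1e-9
  sum(pg$power[sel])
}
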