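# independent oracles and shared fixtures for the test suite

# brute-force Savitzky-Golay: per-point least-squares polyfit on the
# centered window, terminal full windows at the edges
sg_oracle <- function(y, order, window) {
  N <- length(y)
  h <- (window - 1) / 2
  out <- numeric(N)
  for (i in seq_len(N)) {
    if (i <= h) {
      idx <- 1:window; pos <- i
    } else if (i > N - h) {
      idx <- (N - window + 1):N; pos <- i - (N - window)
    } else {
      idx <- (i - h):(i + h); pos <- h + 1
    }
    X <- outer(seq_len(window) - pos, 0:order, `^`)
    out[i] <- lm.fit(X, y[idx])$coefficients[[1L]]
  }
  out
}

# Welch t statistic from first principles
welch_oracle <- function(a, b) {
  va <- var(a) / length(a); vb <- var(b) / length(b)
  t <- (mean(a) - mean(b)) / sqrt(va + vb)
  df <- (va + vb)^2 / (va^2 / (length(a) - 1) + vb^2 / (length(b) - 1))
  list(t = t, df = df, p = 2 * pt(-abs(t), df))
}

extdata <- function(name) system.file("extdata", name, package = "scaffoldlab")

single_ha_model <- function(amplitude = 100, sigma = 8, noise_sd = 0,
                            seed = NULL)
  spectrum_model(bands = band_spec("ha_960", 960, amplitude, sigma),
                 noise_sd = noise_sd, seed = seed)
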