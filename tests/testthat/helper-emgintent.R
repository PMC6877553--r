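# Shared fixtures and independent oracles for the test suite.

# Naive loop-based feature oracle, independent of window_features().
naive_features <- function(x) {
  n <- length(x)
  mu <- sum(x) / n
  v <- 0
  for (xi in x) v <- v + (xi - mu)^2
  v <- v / (n - 1)
  wl <- 0
  for (i in seq_len(n - 1)) wl <- wl + abs(x[i + 1] - x[i])
  iemg <- 0
  for (xi in x) iemg <- iemg + abs(xi)
  rms <- sqrt(sum(x^2) / n)
  # Yule-Walker with explicitly looped biased autocovariances
  c0 <- c1 <- c2 <- 0
  for (i in seq_len(n)) c0 <- c0 + (x[i] - mu)^2
  for (i in seq_len(n - 1)) c1 <- c1 + (x[i] - mu) * (x[i + 1] - mu)
  for (i in seq_len(n - 2)) c2 <- c2 + (x[i] - mu) * (x[i + 2] - mu)
  c0 <- c0 / n; c1 <- c1 / n; c2 <- c2 / n
  det <- c0^2 - c1^2
  if (c0 <= 1e-24) {
    ar1 <- ar2 <- 0
  } else {
    ar1 <- (c0 * c1 - c1 * c2) / det
    ar2 <- (c0 * c2 - c1^2) / det
  }
  c(var = v, wl = wl, iemg = iemg, ar1 = ar1, ar2 = ar2, rms = rms, mav = iemg / n)
}

# Steady-state amplitude gain of a linear filter at frequency f, measured by
# regressing the output (transient discarded) on quadrature sinusoids.
measure_gain <- function(filter_fun, f, fs, dur = 4) {
  t <- seq(0, dur - 1 / fs, by = 1 / fs)
  x <- sin(2 * pi * f * t)
  y <- filter_fun(x)
  keep <- seq(floor(length(y) / 2), length(y))
  s <- sin(2 * pi * f * t[keep])
  cs <- cos(2 * pi * f * t[keep])
  co <- stats::coef(stats::lm(y[keep] ~ s + cs))
  sqrt(co[["s"]]^2 + co[["cs"]]^2)
}

# Wrap a single-channel signal as a 3-channel recording at a given stage.
as_rec <- function(x, fs, stage = "raw") {
  emg_recording(cbind(ta = x, mg = x, lg = x), fs, stage = stage)
}

# Fraction of spectral energy (mean included) inside a frequency band.
band_energy_fraction <- function(x, fs, lo, hi) {
  n <- length(x)
  p <- Mod(stats::fft(x))^2
  freq <- (seq_len(n) - 1) * fs / n
  half <- freq <= fs / 2
  sel <- half & freq >= lo & freq <= hi
  sum(p[sel]) / sum(p[half])
}

tiny_cfg <- function(...) sim_config(n_steps = 6, n_trials = 2, ...)

# Deterministic participant with unit variability for exactness-style tests.
fixed_participant <- function(style = "optimum", cfg = tiny_cfg()) {
  p <- with_seed(99, participant("FX", style, cfg, mvc = c(1, 1, 1)))
  p$act_var[] <- 1
  p
}

# Fake window table with given per-muscle mean envelopes (MVC fraction).
fake_windows <- function(ta, mg, lg, n = 10, n_samples = 300,
                         terrain = "level_ground", participant = "F01") {
  data.frame(participant = participant, style = "optimum", terrain = terrain,
             condition = "OE", trial = 1L, window = seq_len(n),
             label = rep_len(1:3, n), n_samples = n_samples,
             s_ta = ta * n_samples, s_mg = mg * n_samples,
             s_lg = lg * n_samples, stringsAsFactors = FALSE)
}

# Two-class Gaussian blobs for classifier checks.
make_blobs <- function(n = 200, sd = 0.1, gap = 0.6, seed = 1) {
  with_seed(seed, {
    x <- rbind(matrix(stats::rnorm(2 * n, 0, sd), ncol = 2),
               matrix(stats::rnorm(2 * n, gap, sd), ncol = 2))
    colnames(x) <- c("f1", "f2")
    list(x = x, y = rep(c(1L, 2L), each = n))
  })
}

# Cache: default-scale experiment shared by evaluation and acceptance tests.
cached_experiment <- local({
  res <- NULL
  function() {
    if (is.null(res)) {
      res <<- suppressMessages(run_experiment(default_experiment_config(),
                                              seed = 42))
    }
    res
  }
})
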