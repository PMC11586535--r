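make_rec <- function(x, fs = 4000) {
  structure(list(patient_id = "T", site = "left_apex", samples = x,
                 sample_rate = fs), class = "pcg_recording")
}

test_that("a pure sinusoid concentrates energy at its frequency bin", {
  fs <- 4000
  x <- sin(2 * pi * 200 * seq_len(2 * fs) / fs)
  sp <- compute_log_spectrogram(make_rec(x, fs),
                                spectrogram_config(normalization = "none"))
  power <- exp(2 * sp$values)  # per-frame magnitude^2
  target <- which.min(abs(sp$frequencies - 200))
  near <- max(target - 1, 1):min(target + 1, ncol(power))
  frac <- rowSums(power[, near, drop = FALSE]) / rowSums(power)
  expect_gte(mean(frac >= 0.9), 0.95)
})

test_that("an all-zero waveform maps to the log floor", {
  cfg <- spectrogram_config(normalization = "none", log_floor = 1e-6)
  sp <- compute_log_spectrogram(make_rec(numeric(4000)), cfg)
  expect_true(all(sp$values == log(1e-6)))
  # z-scored version remains finite
  spz <- compute_log_spectrogram(make_rec(numeric(4000)),
                                 spectrogram_config())
  expect_true(all(is.finite(spz$values)))
})

test_that("time reversal reverses the frame order", {
  # length chosen so the frame grid is closed under reversal
  n <- 200 + 80 * 60
  set.seed(1)
  x <- sin(2 * pi * 150 * seq_len(n) / 4000) + 0.1 * rnorm(n)
  cfg <- spectrogram_config(normalization = "none")
  fwd <- compute_log_spectrogram(make_rec(x), cfg)$values
  rev_ <- compute_log_spectrogram(make_rec(rev(x)), cfg)$values
  expect_equal(rev_[rev(seq_len(nrow(rev_))), ], fwd, tolerance = 1e-8)
})

test_that("amplitude scaling shifts raw log values and cancels under z-score", {
  set.seed(2)
  x <- stats::rnorm(4000) * 0.1
  raw_cfg <- spectrogram_config(normalization = "none", log_floor = 1e-12)
  a <- compute_log_spectrogram(make_rec(x), raw_cfg)$values
  b <- compute_log_spectrogram(make_rec(3 * x), raw_cfg)$values
  expect_equal(b - a, matrix(log(3), nrow(a), ncol(a)), tolerance = 1e-8)
  z_cfg <- spectrogram_config()
  za <- compute_log_spectrogram(make_rec(x), z_cfg)$values
  zb <- compute_log_spectrogram(make_rec(3 * x), z_cfg)$values
  expect_equal(za, zb, tolerance = 1e-8)
})

test_that("output is finite for any finite input and config is validated", {
  set.seed(3)
  for (i in 1:5) {
    x <- stats::rnorm(3000, sd = 10^stats::runif(1, -6, 2))
    for (norm in c("recording", "bin", "none")) {
      sp <- compute_log_spectrogram(
        make_rec(x), spectrogram_config(normalization = norm))
      expect_true(all(is.finite(sp$values)))
    }
  }
  expect_error(spectrogram_config(hop_length = 300), "hop_length")
  expect_error(spectrogram_config(log_floor = 0), "log_floor")
  expect_error(compute_log_spectrogram(make_rec(numeric(10))), "shorter")
})

test_that("temporal pooling averages adjacent frames", {
  v <- matrix(1:24, nrow = 6)
  p <- caninemurmur:::pool_time(v, 2L)
  expect_equal(nrow(p), 3)
  expect_equal(p[1, ], (v[1, ] + v[2, ]) / 2)
})
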