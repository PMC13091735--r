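test_that("taper power concentrates at the stimulation frequency", {
  fs <- 500
  tax <- seq(-1, 3 - 1 / fs, by = 1 / fs)
  sine <- sin(2 * pi * 40 * tax) * (tax >= 0 & tax <= 1)
  v <- fixture_virtual(matrix(rep(sine, 2), 2, byrow = TRUE))
  m <- power_of_average(v, freqs_hz = c(30, 35, 40))
  pw <- rowMeans(m$values)
  # 7-cycle Hanning response: ~4x over the 35 Hz shoulder, >100x at 30 Hz
  expect_gt(pw[3] / pw[1], 100)
  expect_gt(pw[3] / pw[2], 3)
  expect_lt(pw[3] / pw[2], 5)
  zero <- power_of_average(fixture_virtual(matrix(0, 2, length(tax))),
                           freqs_hz = c(20, 40))
  expect_true(all(zero$values[is.finite(zero$values)] == 0))
  expect_error(power_of_average(v, trial_ids = integer(0)), "empty")
})

test_that("frequencies whose 7-cycle window cannot fit are marked invalid", {
  v <- fixture_virtual(matrix(rnorm(2 * 2000), 2, 2000))
  m <- power_of_average(v, freqs_hz = c(1, 1.5, 40))
  expect_true(all(is.na(m$values[1, ])))   # 7 s window > 4 s epoch
  expect_true(all(is.finite(m$values[3, ])))
})

test_that("averaging many noise trials leaves no spurious 40 Hz peak", {
  worst <- vapply(1:20, function(s) {
    v <- fixture_virtual(withr::with_seed(s, matrix(rnorm(1000 * 2000), 1000)))
    m <- power_of_average(v, freqs_hz = c(35, 37, 40, 43, 45))
    pw <- rowMeans(m$values)
    pw[3] / mean(pw[-3])
  }, numeric(1))
  expect_true(all(worst < 3))
})

test_that("ITPC is exact for identical trials, bounded, and negation-invariant", {
  fs <- 500
  tax <- seq(-1, 3 - 1 / fs, by = 1 / fs)
  sine <- sin(2 * pi * 40 * tax)
  v <- fixture_virtual(matrix(rep(sine, 5), 5, byrow = TRUE))
  m <- itpc_map(v, freqs_hz = c(20, 40), times_s = c(0, 0.5, 1))
  expect_true(all(abs(m$values[is.finite(m$values)] - 1) < 1e-9))
  vn <- fixture_virtual(-v$data)
  mn <- itpc_map(vn, freqs_hz = c(20, 40), times_s = c(0, 0.5, 1))
  expect_equal(mn$values, m$values)
  expect_error(itpc_map(v, trial_ids = 1), "2 trials")
  noisy <- fixture_virtual(withr::with_seed(3, matrix(rnorm(20 * 2000), 20)))
  mno <- itpc_map(noisy, freqs_hz = seq(10, 40, 10), times_s = c(0, 1))
  expect_true(all(mno$values >= 0 & mno$values <= 1, na.rm = TRUE))
})

test_that("ITPC under uniform phase follows the sqrt(pi)/(2 sqrt(n)) law", {
  fs <- 500
  tax <- seq(-1, 3 - 1 / fs, by = 1 / fs)
  n <- 100
  vals <- vapply(1:20, function(s) {
    ph <- withr::with_seed(300 + s, runif(n, 0, 2 * pi))
    dat <- t(vapply(ph, function(p) sin(2 * pi * 40 * tax + p),
                    numeric(length(tax))))
    m <- itpc_map(fixture_virtual(dat), freqs_hz = 40, times_s = 0.5)
    m$values[1, 1]
  }, numeric(1))
  expect_gte(mean(vals < 0.2), 0.95)
  expect_equal(mean(vals), sqrt(pi) / (2 * sqrt(n)), tolerance = 0.25)
})

test_that("power SNR follows its definition on constructed maps", {
  mk_map <- function(vals, freqs) {
    assr:::new_tfr(vals, freqs, seq(0.25, 1, 0.25), "power_of_average", 10)
  }
  freqs <- seq(20, 48, by = 0.5)
  flat <- mk_map(matrix(1, length(freqs), 4), freqs)
  expect_equal(snr_from_power(flat)$snr, 1)
  vals <- matrix(2, length(freqs), 4)
  vals[freqs == 40, ] <- 10
  vals[freqs > 38 & freqs < 42 & freqs != 40, ] <- 100  # transition bins ignored
  expect_equal(snr_from_power(mk_map(vals, freqs))$snr, 5)
  expect_error(snr_from_power(mk_map(matrix(1, 3, 4), c(10, 20, 30))),
               "40")
  itpc_like <- assr:::new_tfr(matrix(1, 3, 4), c(20, 30, 40),
                              seq(0.25, 1, 0.25), "itpc", 10)
  expect_error(snr_from_power(itpc_like), "power_of_average")
})

test_that("power SNR grows with signal amplitude (simulation oracle)", {
  fs <- 500
  tax <- seq(-1, 3 - 1 / fs, by = 1 / fs)
  sine <- sin(2 * pi * 40 * tax) * (tax >= 0 & tax <= 1)
  snrs <- vapply(c(0.1, 0.3, 0.6, 1, 2), function(a) {
    dat <- withr::with_seed(17, matrix(rnorm(20 * length(tax)), 20))
    dat <- sweep(dat, 2, -a * sine)
    snr_from_power(power_of_average(fixture_virtual(dat),
                                    freqs_hz = seq(20, 48, 0.5)))$snr
  }, numeric(1))
  expect_true(all(diff(snrs) > 0))
})

test_that("ITPC ratio follows its definition and exceeds 1 for locked signals", {
  freqs <- c(seq(20, 30, 0.5), 40)
  mk <- function(vals) assr:::new_tfr(vals, freqs, seq(-1, 2, 0.25), "itpc", 50)
  ones <- mk(matrix(1, length(freqs), 13))
  expect_equal(itpc_ratio(ones)$snr, 1)
  vals <- matrix(0.3, length(freqs), 13)
  vals[freqs == 40, ] <- 0.9
  expect_equal(itpc_ratio(mk(vals))$snr, 3)
  fs <- 500
  tax <- seq(-1, 3 - 1 / fs, by = 1 / fs)
  sine <- sin(2 * pi * 40 * tax) * (tax >= 0 & tax <= 1)
  ratios <- vapply(1:20, function(s) {
    dat <- withr::with_seed(500 + s, matrix(rnorm(50 * length(tax), sd = 2), 50))
    dat <- sweep(dat, 2, -sine)
    itpc_ratio(itpc_map(fixture_virtual(dat), freqs_hz = freqs))$snr
  }, numeric(1))
  expect_gte(mean(ratios > 1), 0.95)
})

test_that("trial-count curves are chronological and self-consistent", {
  fs <- 500
  tax <- seq(-1, 3 - 1 / fs, by = 1 / fs)
  sine <- sin(2 * pi * 40 * tax) * (tax >= 0 & tax <= 1)
  dat <- withr::with_seed(9, matrix(rnorm(25 * length(tax)), 25))
  dat <- sweep(dat, 2, -sine)
  v <- fixture_virtual(dat)
  cu <- trial_count_curve(v, bins = c(5, 10, 25), metric = "power_snr",
                          freqs_hz = seq(20, 48, 0.5))
  all_tr <- snr_from_power(power_of_average(v, freqs_hz = seq(20, 48, 0.5)))$snr
  expect_equal(cu$values[3], all_tr)
  expect_equal(cu$selection_rule, "chronological")
  expect_error(trial_count_curve(v, bins = c(1, 5), metric = "itpc_ratio"),
               "at least 2")
  expect_error(trial_count_curve(v, bins = c(10, 50), metric = "power_snr"),
               "exceeds")
  expect_error(trial_count_curve(v, bins = c(10, 5), metric = "power_snr"),
               "increasing")
})

test_that("percent increase uses the documented baselines", {
  expect_equal(percent_increase(2, 2), 0)
  expect_equal(percent_increase(3.05, 1.0), 205)
  expect_equal(percent_increase(2, 1, baseline = "mod1"), 50)
  expect_error(percent_increase(1, 0), "nonzero")
})

test_that("group summaries report mean, SEM and extrema per bin", {
  curves <- data.frame(participant = rep(c("a", "b"), each = 2),
                       modality = "OPM", bin = c(10, 20, 10, 20),
                       value = c(1, 2, 3, 4))
  s <- summarize_group(curves)
  expect_equal(s$mean, c(2, 3))
  expect_equal(s$sem, c(1, 1))
  expect_equal(s$min, c(1, 2))
  expect_equal(s$max, c(3, 4))
  expect_true(all(s$min <= s$mean & s$mean <= s$max))
  single <- summarize_group(curves[curves$participant == "a", ])
  expect_true(all(is.na(single$sem)))
  bad <- rbind(curves, data.frame(participant = "a", modality = "EEG",
                                  bin = 30, value = 1))
  expect_error(summarize_group(bad), "bins differ")
})

test_that("metrics are scale-invariant end to end", {
  fs <- 500
  tax <- seq(-1, 3 - 1 / fs, by = 1 / fs)
  sine <- sin(2 * pi * 40 * tax) * (tax >= 0 & tax <= 1)
  dat <- withr::with_seed(13, matrix(rnorm(20 * length(tax)), 20))
  dat <- sweep(dat, 2, -sine)
  v1 <- fixture_virtual(dat)
  v2 <- fixture_virtual(dat * 7.3)
  f <- seq(20, 48, 0.5)
  expect_equal(snr_from_power(power_of_average(v2, freqs_hz = f))$snr,
               snr_from_power(power_of_average(v1, freqs_hz = f))$snr,
               tolerance = 1e-12)
  fi <- c(seq(20, 30, 0.5), 40)
  expect_equal(itpc_ratio(itpc_map(v2, freqs_hz = fi))$snr,
               itpc_ratio(itpc_map(v1, freqs_hz = fi))$snr,
               tolerance = 1e-12)
})
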