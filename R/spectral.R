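#' Sliding Hanning-taper power of the trial average
#'
#' Averages the selected trials first, then computes time-frequency power of
#' the average with a sliding Hanning taper whose duration adapts to 7
#' cycles per frequency (window length `7/f` s, rounded to an odd sample
#' count). Power is `|coefficient|^2` of the tapered complex demodulation,
#' normalized so a unit-amplitude sinusoid gives peak power 0.25 (amplitude
#' convention of a two-sided spectrum). Frequencies whose 7-cycle window
#' cannot fit within the epoch, and time points where the window spills over
#' the epoch edge, are marked `NA` rather than dropped.
#'
#' @param virtual An `assr_virtual_epochs` (or any list with `data` trials x
#'   samples, `time_axis_s`, `sampling_rate_hz`).
#' @param trial_ids Row indices of trials to use (default all).
#' @param freqs_hz Frequency grid (default 1--60 Hz, step 0.5).
#' @param times_s Analysis time points (default 0.25--1 s, step 0.05).
#' @param n_cycles Taper duration in cycles (default 7).
#' @return Object of class `assr_tfr`: `values` (freq x time, power),
#'   `freqs_hz`, `times_s`, `kind = "power_of_average"`, `n_trials_used`.
#' @export
power_of_average <- function(virtual, trial_ids = NULL,
                             freqs_hz = seq(1, 60, by = 0.5),
                             times_s = seq(0.25, 1, by = 0.05),
                             n_cycles = 7) {
  ids <- trial_ids %||% seq_len(nrow(virtual$data))
  if (length(ids) < 1) stop("empty trial selection")
  avg <- colMeans(virtual$data[ids, , drop = FALSE])
  fs <- virtual$sampling_rate_hz
  tax <- virtual$time_axis_s
  vals <- matrix(NA_real_, length(freqs_hz), length(times_s))
  for (fi in seq_along(freqs_hz)) {
    f <- freqs_hz[fi]
    len <- round(n_cycles / f * fs)
    if (len %% 2 == 0) len <- len + 1
    if (len > length(avg)) next           # window cannot fit: invalid
    half <- (len - 1) / 2
    k <- seq(-half, half)
    taper <- 0.5 * (1 + cos(pi * k / half))
    basis <- taper * exp(-2i * pi * f * k / fs)
    norm <- sum(taper)
    for (ti in seq_along(times_s)) {
      ci <- which.min(abs(tax - times_s[ti]))
      if (ci - half < 1 || ci + half > length(avg)) next
      coef <- sum(avg[(ci - half):(ci + half)] * basis) / norm
      vals[fi, ti] <- Mod(coef)^2
    }
  }
  new_tfr(vals, freqs_hz, times_s, "power_of_average", length(ids))
}

#' Inter-trial phase coherence map
#'
#' Convolves each trial with a Gaussian (Morlet-family) wavelet of 7 cycles
#' (`sigma_t = n_cycles / (2 pi f)`, support truncated at +-3 sigma) and
#' computes `ITPC(f, t) = | mean_trials coef/|coef| |`, the resultant length
#' of the unit phase vectors. Values lie in [0, 1]; 1 means perfect phase
#' locking, and under uniformly random phase the expectation is
#' `sqrt(pi)/(2 sqrt(n))`.
#'
#' @param virtual An `assr_virtual_epochs`.
#' @param trial_ids Trials to use (default all); at least 2.
#' @param freqs_hz Frequency grid (default 1--60 Hz, step 0.1).
#' @param times_s Time grid (default -1--2 s, step 0.25).
#' @param n_cycles Wavelet duration in cycles (default 7).
#' @return An `assr_tfr` with `kind = "itpc"`.
#' @export
itpc_map <- function(virtual, trial_ids = NULL,
                     freqs_hz = seq(1, 60, by = 0.1),
                     times_s = seq(-1, 2, by = 0.25),
                     n_cycles = 7) {
  ids <- trial_ids %||% seq_len(nrow(virtual$data))
  if (length(ids) < 2) {
    stop("ITPC is undefined for fewer than 2 trials")
  }
  x <- virtual$data[ids, , drop = FALSE]
  fs <- virtual$sampling_rate_hz
  tax <- virtual$time_axis_s
  ns <- ncol(x)
  vals <- matrix(NA_real_, length(freqs_hz), length(times_s))
  for (fi in seq_along(freqs_hz)) {
    f <- freqs_hz[fi]
    sigma <- n_cycles / (2 * pi * f)
    half <- round(3 * sigma * fs)
    if (2 * half + 1 > ns) next
    k <- seq(-half, half)
    w <- exp(-(k / fs)^2 / (2 * sigma^2)) * exp(-2i * pi * f * k / fs)
    wre <- Re(w); wim <- Im(w)
    for (ti in seq_along(times_s)) {
      ci <- which.min(abs(tax - times_s[ti]))
      if (ci - half < 1 || ci + half > ns) next
      seg <- x[, (ci - half):(ci + half), drop = FALSE]
      coef <- complex(real = seg %*% wre, imaginary = seg %*% wim)
      m <- Mod(coef)
      ok <- m > 0
      if (!any(ok)) next
      vals[fi, ti] <- Mod(mean(coef[ok] / m[ok]))
    }
  }
  new_tfr(vals, freqs_hz, times_s, "itpc", length(ids))
}

new_tfr <- function(values, freqs_hz, times_s, kind, n_trials_used) {
  if (is.unsorted(freqs_hz, strictly = TRUE)) {
    stop("frequency grid must be strictly increasing")
  }
  structure(list(values = values, freqs_hz = freqs_hz, times_s = times_s,
                 kind = kind, n_trials_used = n_trials_used),
            class = "assr_tfr")
}

#' @export
print.assr_tfr <- function(x, ...) {
  cat(sprintf("<assr_tfr> %s: %d freqs x %d times, %d trials, %.0f%% valid\n",
              x$kind, length(x$freqs_hz), length(x$times_s),
              x$n_trials_used, 100 * mean(is.finite(x$values))))
  invisible(x)
}

#' Spectral signal-to-noise ratio at 40 Hz
#'
#' `SNR = power(40 Hz) / mean power(noise range)`: the 40 Hz power of the
#' trial average, averaged over valid time points in the stimulation window,
#' divided by the mean power over the noise bands 20--38 and 42--48 Hz at
#' the same time points. A linear ratio.
#'
#' @param map An `assr_tfr` of kind `power_of_average`.
#' @param signal_freq_hz Signal frequency (default 40).
#' @param noise_bands_hz List of length-2 noise intervals.
#' @return Object of class `assr_snr`: `snr`, `metric = "power_snr"`,
#'   `n_trials`, `signal_freq_hz`, `noise_bands_hz`.
#' @export
snr_from_power <- function(map, signal_freq_hz = 40,
                           noise_bands_hz = list(c(20, 38), c(42, 48))) {
  stopifnot(inherits(map, "assr_tfr"))
  if (map$kind != "power_of_average") {
    stop("snr_from_power expects a power_of_average map")
  }
  band_ratio(map, signal_freq_hz, noise_bands_hz, "power_snr")
}

#' ITPC ratio at 40 Hz
#'
#' Ratio of ITPC at 40 Hz to the mean ITPC over the 20--30 Hz noise band
#' (kept below the signal to avoid smearing signal into noise), averaged
#' over the stimulation-phase time points (grid points within 0.25--1 s
#' inclusive).
#'
#' @param map An `assr_tfr` of kind `itpc`.
#' @param signal_freq_hz Signal frequency (default 40).
#' @param noise_bands_hz Noise band (default 20--30 Hz).
#' @param time_window_s Stimulation-phase window (default 0.25--1 s).
#' @return An `assr_snr` with `metric = "itpc_ratio"`.
#' @export
itpc_ratio <- function(map, signal_freq_hz = 40,
                       noise_bands_hz = list(c(20, 30)),
                       time_window_s = c(0.25, 1.0)) {
  stopifnot(inherits(map, "assr_tfr"))
  if (map$kind != "itpc") stop("itpc_ratio expects an itpc map")
  band_ratio(map, signal_freq_hz, noise_bands_hz, "itpc_ratio", time_window_s)
}

band_ratio <- function(map, signal_freq_hz, noise_bands_hz, metric,
                       time_window_s = NULL) {
  sig_fi <- which(abs(map$freqs_hz - signal_freq_hz) < 1e-9)
  if (length(sig_fi) != 1) stop("frequency grid is missing the ",
                                signal_freq_hz, " Hz bin")
  noise_fi <- which(vapply(map$freqs_hz, function(f) {
    any(vapply(noise_bands_hz, function(b) f >= b[1] && f <= b[2], logical(1)))
  }, logical(1)))
  if (length(noise_fi) == 0) stop("empty noise band")
  ti <- seq_along(map$times_s)
  if (!is.null(time_window_s)) {
    ti <- which(map$times_s >= time_window_s[1] - 1e-9 &
                  map$times_s <= time_window_s[2] + 1e-9)
  }
  sig_vals <- map$values[sig_fi, ti]
  valid_t <- ti[is.finite(sig_vals)]
  if (length(valid_t) == 0) stop("no valid time points at the signal frequency")
  num <- mean(map$values[sig_fi, valid_t])
  den <- mean(map$values[noise_fi, valid_t], na.rm = TRUE)
  if (!is.finite(den) || den <= 0) stop("noise band has no valid power")
  structure(list(snr = num / den, metric = metric,
                 n_trials = map$n_trials_used,
                 signal_freq_hz = signal_freq_hz,
                 noise_bands_hz = noise_bands_hz),
            class = "assr_snr")
}

#' @export
print.assr_snr <- function(x, ...) {
  cat(sprintf("<assr_snr> %s = %.3f (linear ratio, %d trials)\n",
              x$metric, x$snr, x$n_trials))
  invisible(x)
}

#' Metric as a function of trial count
#'
#' Recomputes a metric from the first `k` retained trials, for each `k` in
#' `bins`, always in chronological order so a `k`-trial bin represents a
#' real experiment with `k` trials. ITPC-based bins start at 10 because
#' ITPC is undefined for a single trial.
#'
#' @param virtual An `assr_virtual_epochs`.
#' @param bins Increasing trial counts; default `c(1, 10, 20, ..., 80)` for
#'   power SNR and `c(10, 20, ..., 80)` for the ITPC ratio.
#' @param metric `"power_snr"` or `"itpc_ratio"`.
#' @param ... Passed to [power_of_average()] / [itpc_map()] (e.g., a
#'   restricted frequency grid).
#' @return Object of class `assr_trial_curve`: data.frame `bins`, `values`,
#'   plus `metric` and `selection_rule = "chronological"`.
#' @export
trial_count_curve <- function(virtual,
                              bins = NULL,
                              metric = c("power_snr", "itpc_ratio"),
                              ...) {
  metric <- match.arg(metric)
  bins <- bins %||% if (metric == "power_snr") c(1, seq(10, 80, by = 10)) else
    seq(10, 80, by = 10)
  if (is.unsorted(bins, strictly = TRUE)) stop("bins must be strictly increasing")
  ntr <- nrow(virtual$data)
  if (max(bins) > ntr) {
    stop("bin of ", max(bins), " trials exceeds the ", ntr, " retained trials")
  }
  if (metric == "itpc_ratio" && min(bins) < 2) {
    stop("ITPC-ratio bins must contain at least 2 trials")
  }
  vals <- vapply(bins, function(k) {
    ids <- seq_len(k)       # first k retained trials, chronological
    if (metric == "power_snr") {
      snr_from_power(power_of_average(virtual, ids, ...))$snr
    } else {
      itpc_ratio(itpc_map(virtual, ids, ...))$snr
    }
  }, numeric(1))
  structure(list(bins = bins, values = vals, metric = metric,
                 selection_rule = "chronological",
                 modality = virtual$modality,
                 participant_id = virtual$participant_id),
            class = "assr_trial_curve")
}

#' Percent increase between two modality values
#'
#' `100 * (v_mod1 - v_mod2) / v_baseline`. The default baseline is the
#' comparison value `v_mod2`, so that e.g. `v1 = 3.05, v2 = 1` gives 205%;
#' `baseline = "mod1"` gives the literal normalization by the first value.
#'
#' @param v_mod1,v_mod2 Metric values (e.g., SNRs) of the two modalities.
#' @param baseline `"mod2"` (default) or `"mod1"`.
#' @return Percent increase (scalar).
#' @export
percent_increase <- function(v_mod1, v_mod2, baseline = c("mod2", "mod1")) {
  baseline <- match.arg(baseline)
  vb <- if (baseline == "mod2") v_mod2 else v_mod1
  if (!is.finite(vb) || vb == 0) stop("baseline value must be nonzero")
  (v_mod1 - v_mod2) / vb * 100
}

#' Group summary of trial-count curves
#'
#' Per bin and modality: mean, standard error of the mean, minimum and
#' maximum over participants. With a single participant the SEM is `NA`
#' (undefined), by convention.
#'
#' @param curves Either a list of `assr_trial_curve` objects or a long
#'   data.frame with columns `participant`, `modality`, `bin`, `value`.
#' @return Data.frame with `modality`, `bin`, `n`, `mean`, `sem`, `min`,
#'   `max`.
#' @export
summarize_group <- function(curves) {
  if (!is.data.frame(curves)) {
    curves <- do.call(rbind, lapply(curves, function(cu) {
      data.frame(participant = cu$participant_id %||% NA_character_,
                 modality = cu$modality %||% NA_character_,
                 bin = cu$bins, value = cu$values, stringsAsFactors = FALSE)
    }))
  }
  by_mod <- split(curves, curves$modality)
  bins_ref <- sort(unique(by_mod[[1]]$bin))
  for (b in by_mod) {
    if (!identical(sort(unique(b$bin)), bins_ref)) {
      stop("bins differ across modalities")
    }
  }
  out <- do.call(rbind, lapply(split(curves, list(curves$modality, curves$bin),
                                     drop = TRUE), function(g) {
    data.frame(modality = g$modality[1], bin = g$bin[1], n = nrow(g),
               mean = mean(g$value),
               sem = if (nrow(g) > 1) stats::sd(g$value) / sqrt(nrow(g)) else NA_real_,
               min = min(g$value), max = max(g$value),
               stringsAsFactors = FALSE)
  }))
  out <- out[order(out$modality, out$bin), ]
  rownames(out) <- NULL
  out
}
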