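#' Stimulus schedule for a simulated session
#'
#' Draws the randomized condition order and stimulus onset times. Successive
#' onsets are separated by the 1 s stimulation plus a uniform inter-trial
#' interval from `iti_range_s`, so default gaps fall in 2.3--2.7 s.
#'
#' @param config An [sim_config()] object.
#' @return Object of class `assr_schedule`: list with `onsets_s`,
#'   `conditions` and `total_duration_s`.
#' @export
make_stimulus_schedule <- function(config) {
  validate_sim_config(config)
  n_tot <- sum(config$n_trials)
  if (n_tot < 1) stop("schedule requires at least one trial")
  with_seed(derive_seed(config$seed, "schedule"), {
    conditions <- sample(rep(names(config$n_trials), config$n_trials))
    gaps <- config$stim_duration_s +
      runif(n_tot - 1, config$iti_range_s[1], config$iti_range_s[2])
    onsets <- config$lead_in_s + c(0, cumsum(gaps))
    structure(list(onsets_s = onsets, conditions = conditions,
                   total_duration_s = onsets[n_tot] + config$lead_out_s),
              class = "assr_schedule")
  })
}

#' Single-trial source waveform
#'
#' Synthesizes the source-space response to one amplitude-modulated tone: a
#' damped oscillatory onset transient (first ~0.25 s) plus a steady-state
#' sinusoid at the modulation frequency, phase-locked to stimulus onset up
#' to `trial_phase`, ramping up over 100 ms and decaying exponentially after
#' stimulus offset. Unit steady-state amplitude; physical scaling happens in
#' [mix_to_sensors()].
#'
#' @param condition `"40Hz"`, `"20Hz"` or `"60Hz"`.
#' @param config An [sim_config()] object.
#' @param trial_phase Phase offset of this trial's steady state (radians).
#' @return Numeric vector covering `[0, stim_duration_s + 0.3]` s at the
#'   native sampling rate, with attribute `"fs"`.
#' @export
synthesize_source_waveform <- function(condition, config, trial_phase = 0) {
  freq <- switch(condition, "40Hz" = 40, "20Hz" = 20, "60Hz" = 60,
                 stop("unknown condition: ", condition))
  fs <- config$sampling_rate_hz
  dur <- config$stim_duration_s
  t <- seq(0, dur + 0.3, by = 1 / fs)
  env <- rep(1, length(t))
  ramp <- t < 0.1
  env[ramp] <- 0.5 * (1 - cos(pi * t[ramp] / 0.1))
  off <- t > dur
  env[off] <- exp(-(t[off] - dur) / 0.05)
  steady <- env * sin(2 * pi * freq * t + trial_phase)
  onr <- config$onset_response
  transient <- onr$amplitude * sin(2 * pi * onr$freq_hz * t) *
    exp(-t / onr$decay_s)
  structure(steady + transient, fs = fs)
}

#' Project a source waveform onto the sensors
#'
#' Applies the fixed per-modality forward pattern: a bilateral dipolar field
#' over the temporal sensor clusters for OPM/SQUID (with the second OPM axis
#' seeing a different projection at reduced gain) and a broad, spatially
#' smeared fronto-central potential for EEG. OPM gains are additionally
#' scaled by `amplitude_factor_vs_squid`. Mixing is linear.
#'
#' @param source Numeric source time series (unit amplitude convention).
#' @param config An [sim_config()] object.
#' @param layout Optional layout; defaults to [sensor_layout()] of `config`.
#' @return Numeric matrix channels x samples in modality units.
#' @export
mix_to_sensors <- function(source, config, layout = NULL) {
  layout <- layout %||% sensor_layout(config)
  if (!is.null(config$n_channels) && nrow(layout) != config$n_channels) {
    stop("layout channel count does not match config")
  }
  gain <- forward_pattern(layout, config$modality, config$second_axis_gain) *
    config$evoked_amplitude * config$amplitude_factor_vs_squid
  outer(gain, as.numeric(source))
}

# 1/f^exponent noise with one-sided amplitude spectral density asd_ref at
# ref_hz; spectrum flattened below floor_hz to keep variance finite
one_over_f_series <- function(n, fs, exponent, asd_ref, ref_hz = 40,
                              floor_hz = 1) {
  m <- stats::nextn(n, c(2, 3, 5))   # composite FFT length, truncate after
  w <- rnorm(m, sd = asd_ref * sqrt(fs / 2))
  f <- seq(0, fs, length.out = m + 1)[1:m]
  f <- pmin(f, fs - f)            # symmetric frequency magnitudes
  gain <- (pmax(f, floor_hz) / ref_hz)^(-exponent / 2)
  (Re(fft(fft(w) * gain, inverse = TRUE)) / m)[seq_len(n)]
}

#' Add sensor noise, background activity and artifacts
#'
#' Adds, in order: (i) white sensor noise with one-sided amplitude spectral
#' density `noise_density`; (ii) 1/f neural background (half shared across
#' channels through smooth random spatial patterns, half channel-specific),
#' with per-channel density `background_density` at 40 Hz; (iii) a mains
#' sinusoid at `line_noise_hz`; (iv) seeded blink events (low-frequency,
#' ocular-weighted) and muscle bursts (band-limited 110--140 Hz on random
#' channels) at `artifact_rates`. Fully deterministic given the config seed.
#'
#' @param clean An [continuous_recording()] (typically the mixed evoked
#'   signal only).
#' @param config An [sim_config()] object.
#' @return A new `assr_recording` with noise and artifacts added.
#' @export
add_noise_and_artifacts <- function(clean, config) {
  if (any(config$noise_density < 0)) stop("noise density must be non-negative")
  fs <- clean$sampling_rate_hz
  nch <- nrow(clean$data)
  n <- ncol(clean$data)
  layout <- clean$channel_info
  x <- clean$data
  with_seed(derive_seed(config$seed, "noise", config$modality), {
    nd <- config$noise_density
    ch_density <- if (length(nd) == 2) runif(nch, nd[1], nd[2]) else
      rep(nd, nch)
    if (any(ch_density > 0)) {
      x <- x + matrix(rnorm(nch * n), nch, n) * (ch_density * sqrt(fs / 2))
    }
    if (config$background_density > 0) {
      bg <- config$background_density / sqrt(2)
      # background level varies smoothly across the head (+-30%)
      ch_bg_scale <- runif(nch, 0.7, 1.3)
      n_src <- 5
      pats <- vapply(seq_len(n_src), function(k) {
        ctr <- c(runif(1, -0.8, 0.8), runif(1, -0.8, 0.8))
        gauss_w(cbind(layout$x, layout$y), ctr, runif(1, 0.3, 0.6))
      }, numeric(nch))
      # unit-norm rows: per-channel shared ASD equals the source ASD
      rn <- sqrt(rowSums(pats^2))
      rn[rn == 0] <- 1
      pats <- pats / rn
      src <- vapply(seq_len(n_src), function(k) {
        one_over_f_series(n, fs, config$background_exponent, bg)
      }, numeric(n))
      x <- x + (ch_bg_scale * pats) %*% t(src)
      for (c in seq_len(nch)) {
        x[c, ] <- x[c, ] + ch_bg_scale[c] *
          one_over_f_series(n, fs, config$background_exponent, bg)
      }
    }
    if (config$line_noise_amplitude > 0) {
      tt <- (seq_len(n) - 1) / fs
      x <- x + rep(1, nch) %o%
        (config$line_noise_amplitude *
           sin(2 * pi * config$line_noise_hz * tt + runif(1, 0, 2 * pi)))
    }
    dur_min <- n / fs / 60
    # blinks: gaussian-shaped low-frequency deflections weighted to the eyes
    n_blink <- rpois(1, config$artifact_rates$blinks_per_min * dur_min)
    if (n_blink > 0) {
      bw <- blink_pattern(layout) * 150 * config$evoked_amplitude *
        config$amplitude_factor_vs_squid
      # asymmetric lid sweep: fast closure, slower reopening
      tpl_t <- seq(0, 0.35, by = 1 / fs)
      tpl <- 0.7 * exp(-((tpl_t - 0.1) / 0.022)^2) +
        0.6 * exp(-((tpl_t - 0.17) / 0.07)^2)
      starts <- sort(sample.int(n - length(tpl), n_blink))
      for (s in starts) {
        idx <- s:(s + length(tpl) - 1)
        x[, idx] <- x[, idx] + bw %o% tpl
      }
    }
    # muscle bursts: 110-140 Hz band-limited noise on a cluster of channels,
    # scaled relative to the ongoing 110-140 Hz activity (white + 1/f tail)
    # so a burst stands out regardless of the modality's noise composition
    n_musc <- rpois(1, config$artifact_rates$muscle_per_min * dur_min)
    if (n_musc > 0 && fs > 300) {
      bt <- signal::butter(4, c(110, 140) / (fs / 2), type = "pass")
      len <- round(0.3 * fs)
      win <- 0.5 * (1 - cos(2 * pi * seq(0, 1, length.out = len)))
      bg_mid <- config$background_density *
        (125 / 40)^(-config$background_exponent / 2)
      amp <- 8 * sqrt((mean(config$noise_density)^2 + bg_mid^2) * 30)
      for (k in seq_len(n_musc)) {
        chs <- sample.int(nch, sample(2:6, 1))
        s <- sample.int(n - len, 1)
        burst <- .filtfilt_mat(bt$b, bt$a, matrix(rnorm(len), len, 1))[, 1]
        burst <- burst / stats::sd(burst) * amp * win
        x[chs, s:(s + len - 1)] <- x[chs, s:(s + len - 1)] +
          rep(1, length(chs)) %o% burst
      }
    }
  })
  continuous_recording(x, fs, layout, clean$events, clean$modality,
                       clean$participant_id)
}

#' Simulate a full continuous ASSR session
#'
#' Generates the stimulus schedule, synthesizes each trial's source waveform
#' (with seeded phase and log-normal amplitude jitter), mixes it to the
#' sensors and adds noise and artifacts. A pure function of the config
#' (including its seed): identical inputs give bit-identical output.
#'
#' @param config An [sim_config()] object.
#' @return An [continuous_recording()] with event markers.
#' @export
simulate_recording <- function(config) {
  validate_sim_config(config)
  layout <- sensor_layout(config)
  schedule <- make_stimulus_schedule(config)
  fs <- config$sampling_rate_hz
  n <- round(schedule$total_duration_s * fs)
  n_tr <- length(schedule$onsets_s)
  src <- numeric(n)
  with_seed(derive_seed(config$seed, "trials"), {
    phases <- rnorm(n_tr, 0, config$phase_jitter_sd_rad)
    amps <- exp(rnorm(n_tr, 0, config$amplitude_jitter_sd))
    for (i in seq_len(n_tr)) {
      w <- synthesize_source_waveform(schedule$conditions[i], config,
                                      phases[i]) * amps[i]
      s0 <- round(schedule$onsets_s[i] * fs) + 1
      idx <- s0:min(s0 + length(w) - 1, n)
      src[idx] <- src[idx] + w[seq_along(idx)]
    }
  })
  events <- data.frame(sample_index = round(schedule$onsets_s * fs) + 1L,
                       condition = schedule$conditions,
                       stringsAsFactors = FALSE)
  clean <- continuous_recording(mix_to_sensors(src, config, layout), fs,
                                layout, events, config$modality,
                                config$participant_id)
  add_noise_and_artifacts(clean, config)
}

#' Magnetic interference from EEG cabling
#'
#' Field at distance `r` from a straight conductor, `B = mu0 * I / (2 pi r)`.
#' The current can be given directly or as a voltage over a resistance
#' (`I = U / R`). With a conservatively rounded vacuum permeability of
#' 1.3e-6 N/A^2, a 100 uV signal over a 1 GOhm amplifier impedance at 5 mm
#' yields about 4.1e-18 T, well below magnetometer noise floors.
#'
#' @param current_a Current in amperes (or `NULL` to use `voltage_v` /
#'   `resistance_ohm`).
#' @param voltage_v,resistance_ohm Alternative specification of the current.
#' @param distance_m Distance from the conductor in meters (> 0).
#' @param mu0 Vacuum permeability in N/A^2.
#' @return Magnetic flux density in tesla.
#' @export
#' @examples
#' estimate_cable_interference(voltage_v = 100e-6, resistance_ohm = 1e9,
#'                             distance_m = 5e-3, mu0 = 1.3e-6)
estimate_cable_interference <- function(current_a = NULL, voltage_v = NULL,
                                        resistance_ohm = NULL, distance_m,
                                        mu0 = 4e-7 * pi) {
  if (distance_m <= 0) stop("distance must be strictly positive")
  if (is.null(current_a)) {
    if (is.null(voltage_v) || is.null(resistance_ohm)) {
      stop("supply current_a or both voltage_v and resistance_ohm")
    }
    if (resistance_ohm <= 0) stop("resistance must be strictly positive")
    current_a <- voltage_v / resistance_ohm
  }
  mu0 * current_a / (2 * pi * distance_m)
}
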