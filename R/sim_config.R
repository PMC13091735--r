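#' Simulation configuration for a synthetic ASSR session
#'
#' Builds the full parameter set for one simulated auditory steady-state
#' session in one measurement modality. Defaults reproduce the acquisition
#' conditions the package targets: 100 trials of 40 Hz amplitude-modulated
#' stimulation plus 4 trials each at 20 and 60 Hz, 1 s stimulation with a
#' 1.3--1.7 s jittered inter-trial interval, and per-modality sensor counts
#' and noise floors (EEG: 56 scalp electrodes + EOG, noise density within
#' 0.4--2.5 uV/sqrt(Hz); OPM: dual-axis temporal sensors at 15--30
#' fT/sqrt(Hz) with evoked amplitude 2.5x SQUID; SQUID: 124 gradiometers at
#' 2--3 fT/sqrt(Hz)).
#'
#' Units are SI throughout: volts for EEG, tesla for OPM/SQUID, seconds and
#' Hz for time and frequency. `noise_density` and `background_density` are
#' one-sided amplitude spectral densities (units/sqrt(Hz)); the background
#' density is referenced at 40 Hz and follows a 1/f^`background_exponent`
#' power law. The 1000 Hz carrier is conceptual only -- the generator
#' synthesizes the response at the modulation rate, never the carrier.
#'
#' @param modality One of `"EEG"`, `"OPM"`, `"SQUID"`.
#' @param n_trials Named integer vector of trials per condition, names in
#'   `c("40Hz", "20Hz", "60Hz")`.
#' @param sampling_rate_hz Native sampling rate. Defaults: 500 (EEG),
#'   4000 (OPM/SQUID).
#' @param stim_duration_s Stimulus duration in seconds.
#' @param iti_range_s Length-2 numeric, uniform jitter range of the
#'   inter-trial interval in seconds.
#' @param carrier_hz Carrier tone frequency (metadata only).
#' @param evoked_amplitude Steady-state amplitude at the best sensor before
#'   the OPM proximity factor, in modality units (V or T).
#' @param amplitude_factor_vs_squid Evoked-amplitude gain relative to SQUID
#'   (applied in the forward mixing; default 2.5 for OPM, 1 otherwise).
#' @param noise_density White sensor-noise amplitude spectral density:
#'   either a scalar applied to every channel or a length-2 range from which
#'   per-channel densities are drawn uniformly (the published noise floors
#'   are across-sensor ranges).
#' @param background_density 1/f neural background amplitude spectral
#'   density at 40 Hz, per channel.
#' @param background_exponent Power-law exponent of the background PSD.
#' @param line_noise_hz,line_noise_amplitude Mains frequency and sinusoid
#'   amplitude added to every channel.
#' @param phase_jitter_sd_rad SD of the trial-to-trial steady-state phase
#'   (radians); 0 gives perfect phase locking.
#' @param amplitude_jitter_sd SD of the log-normal trial amplitude factor.
#' @param onset_response List with `amplitude` (relative to the steady
#'   state), `freq_hz` and `decay_s` of the damped onset transient.
#' @param artifact_rates List with `blinks_per_min` and `muscle_per_min`.
#' @param n_sites Number of dual-axis OPM sensors (10--16); ignored for
#'   EEG/SQUID.
#' @param second_axis_gain Relative gain of the second OPM measurement axis.
#' @param lead_in_s,lead_out_s Recording padding before the first and after
#'   the last stimulus onset (must allow the -1..+3 s epoch window).
#' @param seed Integer seed; identical config + seed gives bit-identical
#'   output.
#' @param participant_id Identifier stored in the recording.
#' @return An object of class `assr_sim_config` (a validated list).
#' @export
#' @examples
#' cfg <- sim_config("OPM", seed = 7)
#' cfg$n_channels
sim_config <- function(modality = c("EEG", "OPM", "SQUID"),
                       n_trials = c("40Hz" = 100L, "20Hz" = 4L, "60Hz" = 4L),
                       sampling_rate_hz = NULL,
                       stim_duration_s = 1.0,
                       iti_range_s = c(1.3, 1.7),
                       carrier_hz = 1000,
                       evoked_amplitude = NULL,
                       amplitude_factor_vs_squid = NULL,
                       noise_density = NULL,
                       background_density = NULL,
                       background_exponent = 1,
                       line_noise_hz = 50,
                       line_noise_amplitude = NULL,
                       phase_jitter_sd_rad = 0.2,
                       amplitude_jitter_sd = 0.2,
                       onset_response = list(amplitude = 1.5, freq_hz = 9,
                                             decay_s = 0.07),
                       artifact_rates = list(blinks_per_min = 18,
                                             muscle_per_min = 1.5),
                       n_sites = 12L,
                       second_axis_gain = 0.6,
                       lead_in_s = 2.0,
                       lead_out_s = 4.0,
                       seed = 1L,
                       participant_id = "sim01") {
  modality <- match.arg(modality)
  defaults <- switch(modality,
    EEG = list(fs = 500, amp = 0.6e-6, fac = 1, noise = c(0.4e-6, 2.5e-6),
               bg = 1.5e-6, line = 3e-6),
    OPM = list(fs = 4000, amp = 7e-15, fac = 2.5, noise = c(15e-15, 30e-15),
               bg = 26e-15, line = 100e-15),
    SQUID = list(fs = 4000, amp = 7e-15, fac = 1, noise = c(2e-15, 3e-15),
                 bg = 20e-15, line = 30e-15))
  cfg <- list(
    modality = modality,
    n_trials = n_trials,
    sampling_rate_hz = sampling_rate_hz %||% defaults$fs,
    stim_duration_s = stim_duration_s,
    iti_range_s = iti_range_s,
    carrier_hz = carrier_hz,
    evoked_amplitude = evoked_amplitude %||% defaults$amp,
    amplitude_factor_vs_squid = amplitude_factor_vs_squid %||% defaults$fac,
    noise_density = noise_density %||% defaults$noise,
    background_density = background_density %||% defaults$bg,
    background_exponent = background_exponent,
    line_noise_hz = line_noise_hz,
    line_noise_amplitude = line_noise_amplitude %||% defaults$line,
    phase_jitter_sd_rad = phase_jitter_sd_rad,
    amplitude_jitter_sd = amplitude_jitter_sd,
    onset_response = onset_response,
    artifact_rates = artifact_rates,
    n_sites = as.integer(n_sites),
    second_axis_gain = second_axis_gain,
    lead_in_s = lead_in_s,
    lead_out_s = lead_out_s,
    seed = as.integer(seed),
    participant_id = participant_id
  )
  class(cfg) <- "assr_sim_config"
  validate_sim_config(cfg)
  layout <- sensor_layout(cfg)
  cfg$n_channels <- nrow(layout)
  cfg
}

validate_sim_config <- function(cfg) {
  stopifnot(inherits(cfg, "assr_sim_config"))
  if (!all(names(cfg$n_trials) %in% c("40Hz", "20Hz", "60Hz"))) {
    stop("n_trials names must be among '40Hz', '20Hz', '60Hz'")
  }
  if (sum(cfg$n_trials) < 1) stop("at least one trial is required")
  if (any(cfg$n_trials < 0)) stop("trial counts must be non-negative")
  if (cfg$iti_range_s[1] > cfg$iti_range_s[2]) {
    stop("iti_range_s lower bound exceeds upper bound")
  }
  pos <- c(cfg$sampling_rate_hz, cfg$stim_duration_s, cfg$iti_range_s,
           cfg$lead_in_s, cfg$lead_out_s)
  if (any(pos <= 0)) stop("rates and durations must be strictly positive")
  if (any(cfg$noise_density < 0)) stop("noise density must be non-negative")
  if (!length(cfg$noise_density) %in% c(1, 2)) {
    stop("noise_density must be a scalar or a length-2 range")
  }
  if (cfg$background_density < 0) stop("background density must be non-negative")
  if (cfg$lead_in_s < 1 || cfg$lead_out_s < 3) {
    stop("lead_in_s must be >= 1 and lead_out_s >= 3 so that every ",
         "-1..+3 s epoch window lies inside the recording")
  }
  if (cfg$modality == "OPM" && (cfg$n_sites < 10 || cfg$n_sites > 16)) {
    stop("OPM n_sites must be between 10 and 16")
  }
  invisible(cfg)
}

#' @export
print.assr_sim_config <- function(x, ...) {
  cat(sprintf("<assr_sim_config> %s, %d channels @ %g Hz, %d trials (%s), seed %d\n",
              x$modality, x$n_channels %||% NA_integer_, x$sampling_rate_hz,
              sum(x$n_trials),
              paste(sprintf("%s:%d", names(x$n_trials), x$n_trials),
                    collapse = " "),
              x$seed))
  invisible(x)
}

#' Read or write a simulation config as YAML
#'
#' Round-trips an [sim_config()] object through a YAML file. Reading
#' re-validates through `sim_config()`, so the round trip is lossless for
#' all fields.
#'
#' @param cfg An `assr_sim_config`.
#' @param path File path.
#' @return `read_sim_config()` returns an `assr_sim_config`;
#'   `write_sim_config()` returns `path` invisibly.
#' @export
write_sim_config <- function(cfg, path) {
  validate_sim_config(cfg)
  x <- unclass(cfg)
  x$n_channels <- NULL
  x$n_trials <- as.list(x$n_trials)
  yaml::write_yaml(x, path)
  invisible(path)
}

#' @rdname write_sim_config
#' @export
read_sim_config <- function(path) {
  x <- yaml::read_yaml(path)
  x$n_trials <- unlist(x$n_trials)
  do.call(sim_config, x)
}
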