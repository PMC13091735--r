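#' Segment a recording into stimulus-locked epochs
#'
#' Cuts one 4 s epoch per 40 Hz event, from 1 s before to 3 s after stimulus
#' onset, half-open at the right edge so the sample count is exactly
#' `4 * sampling_rate_hz`. Trials at 20 and 60 Hz are task catch trials and
#' are excluded from the ASSR pipeline.
#'
#' @param recording An [continuous_recording()].
#' @param conditions Conditions to keep (default `"40Hz"`).
#' @return An [epoch_set()] at the native sampling rate.
#' @export
epoch_recording <- function(recording, conditions = "40Hz") {
  fs <- recording$sampling_rate_hz
  ev <- recording$events
  ev <- ev[ev$condition %in% conditions, , drop = FALSE]
  if (nrow(ev) == 0) stop("no events with the requested condition(s)")
  n_samp <- 4L * fs
  starts <- ev$sample_index - fs
  if (any(starts < 1) || any(starts + n_samp - 1 > ncol(recording$data))) {
    i <- which(starts < 1 | starts + n_samp - 1 > ncol(recording$data))[1]
    stop("event at sample ", ev$sample_index[i],
         " is too close to the recording edge to epoch")
  }
  data <- array(0, dim = c(nrow(ev), nrow(recording$data), n_samp))
  for (i in seq_len(nrow(ev))) {
    data[i, , ] <- recording$data[, starts[i]:(starts[i] + n_samp - 1)]
  }
  epoch_set(data, seq(-1, 3 - 1 / fs, by = 1 / fs), fs, ev$condition,
            seq_len(nrow(ev)), recording$channel_info, recording$modality,
            recording$participant_id)
}

#' Downsample epochs
#'
#' Anti-alias low-pass filtering (zero-phase order-8 Butterworth at 80% of
#' the target Nyquist) followed by integer decimation. The stimulus-onset
#' sample (t = 0) is preserved exactly.
#'
#' @param epochs An [epoch_set()].
#' @param target_hz Target rate; must divide the current rate.
#' @return Resampled `assr_epochs`.
#' @export
resample_epochs <- function(epochs, target_hz = 500) {
  fs <- epochs$sampling_rate_hz
  if (target_hz > fs) stop("upsampling is not supported")
  if (target_hz == fs) return(epochs)
  fac <- fs / target_hz
  if (abs(fac - round(fac)) > 1e-9) {
    stop("target rate must divide the current rate")
  }
  fac <- round(fac)
  lp <- signal::butter(8, 0.8 * target_hz / fs, type = "low")
  x <- zp_filter(epochs$data, lp$b, lp$a)
  keep <- seq(1, dim(x)[3], by = fac)
  epoch_set(x[, , keep, drop = FALSE], epochs$time_axis_s[keep], target_hz,
            epochs$condition_labels, epochs$kept_trial_ids,
            epochs$channel_info, epochs$modality, epochs$participant_id)
}

#' Re-reference EEG epochs to the common average
#'
#' Subtracts, at every sample, the mean over retained scalp channels. EOG
#' channels are excluded from the mean (but still re-referenced). A guard
#' rejects magnetic modalities, where referencing is meaningless.
#'
#' @param epochs An EEG [epoch_set()].
#' @return Re-referenced `assr_epochs`.
#' @export
rereference_average <- function(epochs) {
  if (epochs$modality != "EEG") {
    stop("average re-referencing applies to EEG only, not ", epochs$modality)
  }
  scalp <- which(epochs$channel_info$region != "eog")
  d <- epochs$data
  ref <- 0
  for (c in scalp) ref <- ref + d[, c, ]          # trials x samples
  ref <- ref / length(scalp)
  for (c in seq_len(dim(d)[2])) d[, c, ] <- d[, c, ] - ref
  replace_data(epochs, d)
}

#' Flag trials with high-frequency muscle activity
#'
#' Band-passes a pseudo-dataset at 110--140 Hz, computes each trial's RMS
#' across channels and flags trials whose robust z-score (median/MAD)
#' exceeds `threshold`. Must run on native-rate data: after downsampling to
#' 500 Hz the band no longer exists.
#'
#' @param epochs An [epoch_set()] with Nyquist above 140 Hz.
#' @param threshold Robust z-score threshold (default 4).
#' @return Integer vector of flagged trial ids (values of `kept_trial_ids`).
#' @export
detect_muscle_trials <- function(epochs, threshold = 4) {
  if (epochs$sampling_rate_hz / 2 <= 140) {
    stop("Nyquist below 140 Hz: run the muscle screen before resampling")
  }
  hf <- bandpass_filter(epochs, 110, 140)
  d <- dim(hf$data)
  m <- matrix(hf$data, d[1], d[2] * d[3])
  rms <- sqrt(rowMeans(m^2))
  epochs$kept_trial_ids[robust_z(rms) > threshold]
}

#' Flag variance-outlier trials and bad channels
#'
#' On a 0.5--80 Hz pseudo-dataset, computes per-trial and per-channel
#' variance; robust z-scores above `threshold` are flagged, and channels
#' with variance below `flat_ratio` times the median channel variance are
#' flagged as flat.
#'
#' @param epochs An [epoch_set()].
#' @param threshold Robust z-score threshold (default 4).
#' @param flat_ratio Relative variance floor for flat channels.
#' @return List with `bad_trials` (trial ids) and `bad_channels` (indices).
#' @export
detect_variance_outliers <- function(epochs, threshold = 4,
                                     flat_ratio = 1e-6) {
  hi <- min(80, 0.9 * epochs$sampling_rate_hz / 2)
  bb <- bandpass_filter(epochs, 0.5, hi)
  d <- dim(bb$data)
  m <- matrix(bb$data, d[1], d[2] * d[3])   # columns: channel fastest
  trial_var <- (rowSums(m^2) - rowSums(m)^2 / ncol(m)) / (ncol(m) - 1)
  s1 <- colSums(m); s2 <- colSums(m^2)
  chan <- rep(seq_len(d[2]), d[3])
  cs1 <- tapply(s1, chan, sum); cs2 <- tapply(s2, chan, sum)
  nn <- d[1] * d[3]
  chan_var <- as.numeric((cs2 - cs1^2 / nn) / (nn - 1))
  bad_trials <- epochs$kept_trial_ids[robust_z(trial_var) > threshold]
  screenable <- epochs$channel_info$region != "eog"
  # channel variances are right-skewed across a heterogeneous layout;
  # screen on the log scale so genuine spatial gain variation is tolerated
  bad_ch <- which(screenable &
                    (robust_z(log(pmax(chan_var, .Machine$double.xmin))) > threshold |
                       chan_var < flat_ratio * stats::median(chan_var[screenable])))
  list(bad_trials = bad_trials, bad_channels = bad_ch)
}

#' Run the full preprocessing chain
#'
#' Fixed stage order: epoch (40 Hz trials) -> muscle screen at the native
#' rate -> downsample to 500 Hz -> average re-reference (EEG only) -> notch
#' 49--51 Hz -> variance/flat screen -> removal of flagged trials and
#' channels -> ICA ocular cleanup -> 5--60 Hz band-pass. All removals are
#' logged in a rejection report.
#'
#' @param recording An [continuous_recording()].
#' @param params List of stage parameters; see Details. Recognized entries:
#'   `target_fs` (500), `notch_band` (c(49, 51)), `final_band` (c(5, 60)),
#'   `muscle_threshold` (4), `variance_threshold` (4), `flat_ratio` (1e-6),
#'   `ica` (TRUE), `ica_corr_threshold` (0.7), `ica_frontal_ratio` (4),
#'   `ica_n_components` (30).
#' @return List with `epochs` (cleaned 5--60 Hz, 500 Hz `assr_epochs`) and
#'   `report` (class `assr_rejection_report`: `bad_trials` data.frame with
#'   id and reason, `bad_channels`, `removed_component_count`).
#' @export
run_preprocessing <- function(recording, params = list()) {
  p <- utils::modifyList(list(
    target_fs = 500, notch_band = c(49, 51), final_band = c(5, 60),
    muscle_threshold = 4, variance_threshold = 4, flat_ratio = 1e-6,
    ica = TRUE, ica_corr_threshold = 0.7, ica_frontal_ratio = 4,
    ica_n_components = 30, ica_seed = 1L), params)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("preprocessing stage '", name, "': ", conditionMessage(e),
           call. = FALSE)
    })
  }
  ep <- stage("epoch", epoch_recording(recording))
  muscle_ids <- stage("muscle screen",
                      detect_muscle_trials(ep, p$muscle_threshold))
  ep <- stage("resample", resample_epochs(ep, p$target_fs))
  if (ep$modality == "EEG") {
    ep <- stage("rereference", rereference_average(ep))
  }
  ep <- stage("notch", notch_filter(ep, p$notch_band))
  vo <- stage("variance screen",
              detect_variance_outliers(ep, p$variance_threshold, p$flat_ratio))
  bad_trials <- data.frame(
    id = c(muscle_ids, setdiff(vo$bad_trials, muscle_ids)),
    reason = c(rep("muscle", length(muscle_ids)),
               rep("variance", length(setdiff(vo$bad_trials, muscle_ids)))),
    stringsAsFactors = FALSE)
  keep_tr <- which(!ep$kept_trial_ids %in% bad_trials$id)
  keep_ch <- setdiff(seq_len(n_channels(ep)), vo$bad_channels)
  bad_ch_labels <- ep$channel_info$label[vo$bad_channels]
  ep <- subset_epochs(ep, trials = keep_tr, channels = keep_ch)
  removed_comps <- 0L
  if (isTRUE(p$ica)) {
    ic <- stage("ica", ica_clean(ep, corr_threshold = p$ica_corr_threshold,
                                 frontal_ratio = p$ica_frontal_ratio,
                                 n_components = p$ica_n_components,
                                 seed = p$ica_seed))
    ep <- ic$epochs
    removed_comps <- ic$removed_component_count
  }
  ep <- stage("bandpass", bandpass_filter(ep, p$final_band[1], p$final_band[2]))
  report <- structure(list(bad_trials = bad_trials,
                           bad_channels = bad_ch_labels,
                           removed_component_count = removed_comps,
                           n_trials_in = sum(recording$events$condition ==
                                               "40Hz"),
                           n_trials_out = n_trials(ep)),
                      class = "assr_rejection_report")
  list(epochs = ep, report = report)
}

#' @export
print.assr_rejection_report <- function(x, ...) {
  cat(sprintf("<rejection report> %d bad trials (%s), %d bad channels, %d ICA components removed\n",
              nrow(x$bad_trials),
              if (nrow(x$bad_trials)) paste(table(x$bad_trials$reason),
                                            names(table(x$bad_trials$reason)),
                                            collapse = ", ") else "none",
              length(x$bad_channels), x$removed_component_count))
  invisible(x)
}

#' Serialize a rejection report to JSON
#'
#' @param report An `assr_rejection_report`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_rejection_report <- function(report, path) {
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
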