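#' Continuous multichannel recording
#'
#' Container for a continuous recording: a channels x samples matrix with
#' sampling rate, channel metadata and stimulus event markers. Sample `i`
#' corresponds to time `(i - 1) / sampling_rate_hz` seconds.
#'
#' @param data Numeric matrix, channels x samples, in modality units
#'   (V or T).
#' @param sampling_rate_hz Sampling rate in Hz.
#' @param channel_info Data.frame as returned by [sensor_layout()]; one row
#'   per channel.
#' @param events Data.frame with columns `sample_index` (1-based) and
#'   `condition` (one of `"40Hz"`, `"20Hz"`, `"60Hz"`).
#' @param modality `"EEG"`, `"OPM"` or `"SQUID"`.
#' @param participant_id Identifier.
#' @return Object of class `assr_recording`.
#' @export
continuous_recording <- function(data, sampling_rate_hz, channel_info,
                                 events, modality, participant_id = "p01") {
  stopifnot(is.matrix(data), nrow(channel_info) == nrow(data))
  events <- events[order(events$sample_index), , drop = FALSE]
  fs <- sampling_rate_hz
  bad <- events$sample_index - fs < 1 |
    events$sample_index + 3 * fs > ncol(data)
  if (any(bad)) {
    stop("event(s) at sample ", paste(events$sample_index[bad], collapse = ", "),
         " too close to the recording edge for a -1..+3 s epoch window")
  }
  structure(list(data = data, sampling_rate_hz = fs,
                 channel_info = channel_info, events = events,
                 modality = modality, participant_id = participant_id),
            class = "assr_recording")
}

#' @export
print.assr_recording <- function(x, ...) {
  cat(sprintf("<assr_recording> %s '%s': %d channels x %d samples @ %g Hz, %d events\n",
              x$modality, x$participant_id, nrow(x$data), ncol(x$data),
              x$sampling_rate_hz, nrow(x$events)))
  invisible(x)
}

#' Epoched trials
#'
#' Container for segmented data: a trials x channels x samples array with a
#' uniform time axis anchored at stimulus onset (t = 0). `kept_trial_ids`
#' are the original chronological trial indices and stay strictly increasing
#' through every rejection stage.
#'
#' @param data Numeric array, trials x channels x samples.
#' @param time_axis_s Numeric vector of sample times relative to onset.
#' @param sampling_rate_hz Sampling rate in Hz.
#' @param condition_labels Character vector, one per trial.
#' @param kept_trial_ids Integer vector of original chronological indices.
#' @param channel_info Channel metadata data.frame.
#' @param modality,participant_id Metadata.
#' @return Object of class `assr_epochs`.
#' @export
epoch_set <- function(data, time_axis_s, sampling_rate_hz, condition_labels,
                      kept_trial_ids, channel_info, modality,
                      participant_id = "p01") {
  stopifnot(length(dim(data)) == 3,
            dim(data)[3] == length(time_axis_s),
            dim(data)[1] == length(condition_labels),
            dim(data)[1] == length(kept_trial_ids),
            dim(data)[2] == nrow(channel_info))
  if (is.unsorted(kept_trial_ids, strictly = TRUE)) {
    stop("kept_trial_ids must be strictly increasing (chronology preserved)")
  }
  step <- diff(time_axis_s)
  if (max(abs(step - 1 / sampling_rate_hz)) > 1e-9) {
    stop("time axis must be uniform with step 1/sampling_rate_hz")
  }
  structure(list(data = data, time_axis_s = time_axis_s,
                 sampling_rate_hz = sampling_rate_hz,
                 condition_labels = condition_labels,
                 kept_trial_ids = as.integer(kept_trial_ids),
                 channel_info = channel_info, modality = modality,
                 participant_id = participant_id),
            class = "assr_epochs")
}

#' @export
print.assr_epochs <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<assr_epochs> %s '%s': %d trials x %d channels x %d samples @ %g Hz, t in [%.3g, %.3g] s\n",
              x$modality, x$participant_id, d[1], d[2], d[3],
              x$sampling_rate_hz, min(x$time_axis_s), max(x$time_axis_s)))
  invisible(x)
}

#' Number of trials / channels in an epoch set
#'
#' @param epochs An [epoch_set()].
#' @return Integer count.
#' @export
n_trials <- function(epochs) dim(epochs$data)[1]

#' @rdname n_trials
#' @export
n_channels <- function(epochs) dim(epochs$data)[2]

#' Subset an epoch set by trials and/or channels
#'
#' Keeps metadata (labels, ids, channel info) consistent with the data.
#'
#' @param epochs An [epoch_set()].
#' @param trials,channels Index vectors (default: keep all).
#' @return An `assr_epochs`.
#' @export
subset_epochs <- function(epochs, trials = NULL, channels = NULL) {
  tr <- trials %||% seq_len(n_trials(epochs))
  ch <- channels %||% seq_len(n_channels(epochs))
  epoch_set(epochs$data[tr, ch, , drop = FALSE], epochs$time_axis_s,
            epochs$sampling_rate_hz, epochs$condition_labels[tr],
            epochs$kept_trial_ids[tr],
            epochs$channel_info[ch, , drop = FALSE],
            epochs$modality, epochs$participant_id)
}

#' Replace the data array of an epoch set, preserving metadata
#'
#' @param epochs An [epoch_set()].
#' @param data Replacement array with the same dimensions.
#' @return The updated object.
#' @export
replace_data <- function(epochs, data) {
  epochs$data <- data
  epochs
}

#' Read or write epochs / recordings
#'
#' Thin serialization wrappers for the package's in-memory containers.
#'
#' @param x An `assr_epochs` or `assr_recording` object.
#' @param path File path (RDS).
#' @return `read_epochs()` returns the stored object; `write_epochs()`
#'   returns `path` invisibly.
#' @export
write_epochs <- function(x, path) {
  saveRDS(x, path)
  invisible(path)
}

#' @rdname write_epochs
#' @export
read_epochs <- function(path) readRDS(path)
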