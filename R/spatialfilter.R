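#' Select the comparable channel subset
#'
#' For OPM and SQUID, returns the channels of the 5 left + 5 right sensor
#' sites closest to the ears among the `temporal`-tagged positions (both
#' axes of a dual-axis OPM site are retained, so the OPM subset has 2
#' channels per site). For EEG, returns the `n` electrodes with the highest
#' group-average 40 Hz response amplitude (EOG excluded), which on realistic
#' topographies is a fronto-central set.
#'
#' @param epochs An [epoch_set()].
#' @param n Number of sites/electrodes (default 10).
#' @param topography For EEG: numeric vector of per-channel 40 Hz amplitudes
#'   (group average; see [topography_40hz()]). Ignored for OPM/SQUID.
#' @return An `assr_epochs` restricted to the subset.
#' @export
select_channel_subset <- function(epochs, n = 10, topography = NULL) {
  info <- epochs$channel_info
  if (epochs$modality %in% c("OPM", "SQUID")) {
    sel <- integer(0)
    for (sgn in c(-1, 1)) {
      side <- which(info$region == "temporal" & sign(info$x) == sgn)
      sites <- unique(info$site[side])
      if (length(sites) < n / 2) {
        stop("fewer temporal sites (", length(sites), ") than requested on ",
             if (sgn < 0) "left" else "right", " side")
      }
      # match sites to the canonical temporal arc positions, greedily and
      # uniquely (topographic matching across sensor systems)
      ref <- temporal_arc(n / 2, sgn)
      keep_sites <- integer(0)
      avail <- sites
      for (r in seq_len(nrow(ref))) {
        dd <- vapply(avail, function(s) {
          i <- which(info$site == s)[1]
          sqrt((info$x[i] - ref[r, 1])^2 + (info$y[i] - ref[r, 2])^2)
        }, numeric(1))
        pick <- avail[which.min(dd)]
        keep_sites <- c(keep_sites, pick)
        avail <- setdiff(avail, pick)
      }
      sel <- c(sel, which(info$site %in% keep_sites))
    }
  } else {
    if (is.null(topography)) topography <- topography_40hz(epochs)
    if (length(topography) != nrow(info)) {
      stop("topography length must equal channel count")
    }
    cand <- which(info$region != "eog")
    if (length(cand) < n) stop("fewer channels (", length(cand),
                               ") than requested (", n, ")")
    sel <- cand[order(topography[cand], decreasing = TRUE)][seq_len(n)]
  }
  subset_epochs(epochs, channels = sort(sel))
}

#' Per-channel 40 Hz response amplitude
#'
#' RMS of the 39--41 Hz band-passed trial average in the 0.25--1 s
#' stimulation window, per channel. Averaged over participants, this is the
#' topography used to pick the EEG electrode subset.
#'
#' @param epochs An [epoch_set()].
#' @return Numeric vector, one amplitude per channel.
#' @export
topography_40hz <- function(epochs) {
  nb <- bandpass_filter(epochs, 39, min(41, 0.9 * epochs$sampling_rate_hz / 2))
  avg <- apply(nb$data, c(2, 3), mean)
  win <- epochs$time_axis_s >= 0.25 & epochs$time_axis_s <= 1
  sqrt(rowMeans(avg[, win, drop = FALSE]^2))
}

#' Fit the canonical-correlation spatial filter
#'
#' Computes the channel weights that maximize the covariance between
#' band-limited single trials and the band-limited trial average: both sides
#' are band-passed 39--41 Hz and restricted to the 0.25--1 s stimulation
#' window; the single trials (concatenated over trials) form one multivariate
#' set and the time-locked average, repeated per trial, the other. The first
#' canonical weight vector for the single-trial side is returned, with ridge
#' regularization `lambda` (relative to the mean channel variance) on both
#' covariances for rank-deficient data (e.g., average-referenced EEG). The
#' weight sign is arbitrary at this stage and fixed later by
#' [fix_polarity()].
#'
#' @param epochs An [epoch_set()] (the cleaned 5--60 Hz data).
#' @param fit_band_hz Band for the fit (default 39--41 Hz).
#' @param fit_window_s Time window of stimulation used for the fit.
#' @param lambda Relative ridge parameter (default 1e-6).
#' @return Object of class `assr_spatial_filter`: `weights` (unit norm),
#'   `polarity_sign` (+1 until corrected), `fit_band_hz`, `fit_window_s`,
#'   `canonical_correlation_value`.
#' @export
fit_cca_filter <- function(epochs, fit_band_hz = c(39, 41),
                           fit_window_s = c(0.25, 1.0), lambda = 1e-6) {
  nch <- n_channels(epochs)
  ntr <- n_trials(epochs)
  win <- epochs$time_axis_s >= fit_window_s[1] &
    epochs$time_axis_s <= fit_window_s[2]
  if (!any(win)) stop("empty fit window")
  if (nch == 1) {
    return(new_spatial_filter(1, fit_band_hz, fit_window_s, 1))
  }
  if (ntr < 2) stop("canonical-correlation fit requires at least 2 trials")
  bp <- bandpass_filter(epochs, fit_band_hz[1],
                        min(fit_band_hz[2], 0.95 * epochs$sampling_rate_hz / 2))
  xw <- bp$data[, , win, drop = FALSE]          # trials x channels x time
  avg <- apply(xw, c(2, 3), mean)               # channels x time
  nt <- sum(win)
  x <- matrix(aperm(xw, c(2, 3, 1)), nrow = nch)       # ch x (time*trials)
  y <- matrix(rep(avg, ntr), nrow = nch)               # average per trial
  x <- x - rowMeans(x)
  y <- y - rowMeans(y)
  nobs <- ncol(x)
  cxx <- tcrossprod(x) / (nobs - 1)
  cyy <- tcrossprod(y) / (nobs - 1)
  cxy <- tcrossprod(x, y) / (nobs - 1)
  rx <- lambda * mean(diag(cxx))
  ry <- lambda * mean(diag(cyy))
  if (rx <= 0 || ry <= 0) {
    stop("degenerate covariance; supply data with nonzero variance")
  }
  cxx_r <- cxx + diag(rx, nch)
  cyy_r <- cyy + diag(ry, nch)
  ex <- eigen(cxx_r, symmetric = TRUE)
  if (min(ex$values) <= 0) {
    stop("channel covariance not positive definite even after ridge; ",
         "increase lambda")
  }
  cxx_isqrt <- ex$vectors %*% (t(ex$vectors) / sqrt(ex$values))
  k <- cxx_isqrt %*% cxy %*% solve(cyy_r, t(cxy)) %*% cxx_isqrt
  ek <- eigen((k + t(k)) / 2, symmetric = TRUE)
  w <- as.numeric(cxx_isqrt %*% ek$vectors[, 1])
  w <- w / sqrt(sum(w^2))
  rho <- sqrt(max(0, min(1, ek$values[1])))
  new_spatial_filter(w, fit_band_hz, fit_window_s, rho)
}

new_spatial_filter <- function(weights, fit_band_hz, fit_window_s, rho,
                               polarity_sign = 1L) {
  if (all(weights == 0)) stop("spatial filter weights must not be all zero")
  structure(list(weights = weights, polarity_sign = polarity_sign,
                 fit_band_hz = fit_band_hz, fit_window_s = fit_window_s,
                 canonical_correlation_value = rho),
            class = "assr_spatial_filter")
}

#' @export
print.assr_spatial_filter <- function(x, ...) {
  cat(sprintf("<assr_spatial_filter> %d weights, rho = %.3f, sign %+d, band %g-%g Hz, window %g-%g s\n",
              length(x$weights), x$canonical_correlation_value,
              x$polarity_sign, x$fit_band_hz[1], x$fit_band_hz[2],
              x$fit_window_s[1], x$fit_window_s[2]))
  invisible(x)
}

#' Apply a spatial filter to produce the virtual channel
#'
#' `virtual(t, trial) = polarity_sign * sum_c w_c x_c(t, trial)`, applied to
#' the full analysis band (not only the fit band).
#'
#' @param epochs An [epoch_set()] whose channel count matches the weights.
#' @param spec An `assr_spatial_filter`.
#' @return Object of class `assr_virtual_epochs`: `data` (trials x samples),
#'   `time_axis_s`, `sampling_rate_hz`, `kept_trial_ids`, `filter`,
#'   `modality`, `participant_id`.
#' @export
apply_spatial_filter <- function(epochs, spec) {
  nch <- n_channels(epochs)
  if (length(spec$weights) != nch) {
    stop("filter has ", length(spec$weights), " weights but data has ",
         nch, " channels")
  }
  d <- dim(epochs$data)
  flat <- matrix(aperm(epochs$data, c(2, 3, 1)), nrow = d[2])
  v <- spec$polarity_sign * as.numeric(crossprod(flat, spec$weights))
  vd <- t(matrix(v, nrow = d[3]))
  structure(list(data = vd, time_axis_s = epochs$time_axis_s,
                 sampling_rate_hz = epochs$sampling_rate_hz,
                 kept_trial_ids = epochs$kept_trial_ids,
                 condition_labels = epochs$condition_labels,
                 filter = spec, modality = epochs$modality,
                 participant_id = epochs$participant_id),
            class = "assr_virtual_epochs")
}

#' @export
print.assr_virtual_epochs <- function(x, ...) {
  cat(sprintf("<assr_virtual_epochs> %s '%s': %d trials x %d samples @ %g Hz\n",
              x$modality, x$participant_id, nrow(x$data), ncol(x$data),
              x$sampling_rate_hz))
  invisible(x)
}

#' Extrema template from a grand-average waveform
#'
#' Locates local minima and maxima of a grand-average time course (plain
#' mean over participants and channels, computed *without* the spatial
#' filter) by sign changes of the first difference, restricted to the
#' stimulation window. Same-type extrema closer than `min_separation_s`
#' (default one 40 Hz cycle, 25 ms) are merged keeping the larger magnitude.
#'
#' @param grand_average Numeric vector (one value per epoch sample).
#' @param time_axis_s Time axis matching `grand_average`.
#' @param window Time window to search (default the 0--1 s stimulation).
#' @param min_separation_s Minimum separation between same-type extrema.
#' @return Data.frame with `sample_index` (into the epoch) and `type`
#'   (`"min"`/`"max"`).
#' @export
build_extrema_template <- function(grand_average, time_axis_s,
                                   window = c(0, 1),
                                   min_separation_s = 0.025) {
  stopifnot(length(grand_average) == length(time_axis_s))
  dx <- diff(grand_average)
  s <- sign(dx)
  # indices where the slope changes sign (interior extrema)
  idx <- which(s[-1] != s[-length(s)] & s[-1] != 0) + 1
  type <- ifelse(s[idx - 1] > 0, "max", "min")
  inwin <- time_axis_s[idx] >= window[1] & time_axis_s[idx] <= window[2]
  idx <- idx[inwin]
  type <- type[inwin]
  if (length(idx) == 0) {
    stop("no local extrema in the window (constant or monotone input)")
  }
  # merge same-type extrema closer than the separation, with one sample of
  # slack so the quantized peak positions of a sampled sinusoid (which
  # alternate around the true period) survive a one-cycle separation
  dt <- stats::median(diff(time_axis_s))
  keep <- logical(length(idx))
  for (ty in c("min", "max")) {
    cand <- which(type == ty)
    cand <- cand[order(abs(grand_average[idx[cand]]), decreasing = TRUE)]
    taken <- numeric(0)
    for (j in cand) {
      tj <- time_axis_s[idx[j]]
      if (all(abs(tj - taken) >= min_separation_s - dt - 1e-12)) {
        keep[j] <- TRUE
        taken <- c(taken, tj)
      }
    }
  }
  out <- data.frame(sample_index = idx[keep], type = type[keep],
                    stringsAsFactors = FALSE)
  out[order(out$sample_index), ]
}

#' Fix the polarity of a virtual channel
#'
#' The canonical-correlation weights have an arbitrary sign. Following the
#' template of extrema from the grand average (see
#' [build_extrema_template()]), the individual's trial-average virtual
#' channel is evaluated at the template minima and maxima; if the mean over
#' minima exceeds the mean over maxima, the data are multiplied by -1. The
#' applied sign is recorded in the filter provenance. Idempotent.
#'
#' @param virtual An `assr_virtual_epochs`.
#' @param extrema_template Data.frame from [build_extrema_template()].
#' @return The polarity-corrected `assr_virtual_epochs`.
#' @export
fix_polarity <- function(virtual, extrema_template) {
  if (nrow(extrema_template) == 0) stop("extrema template is empty")
  if (any(extrema_template$sample_index < 1) ||
      any(extrema_template$sample_index > ncol(virtual$data))) {
    stop("template sample index out of epoch range")
  }
  avg <- colMeans(virtual$data)
  at <- function(ty) mean(avg[extrema_template$sample_index[
    extrema_template$type == ty]])
  if (at("min") > at("max")) {
    virtual$data <- -virtual$data
    virtual$filter$polarity_sign <- -1L * virtual$filter$polarity_sign
  }
  virtual
}

#' Serialize a spatial filter to JSON
#'
#' @param spec An `assr_spatial_filter`.
#' @param path Output file.
#' @return `path` invisibly; `read_spatial_filter()` returns the filter.
#' @export
write_spatial_filter <- function(spec, path) {
  jsonlite::write_json(unclass(spec), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_spatial_filter
#' @export
read_spatial_filter <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  new_spatial_filter(x$weights, x$fit_band_hz, x$fit_window_s,
                     x$canonical_correlation_value, x$polarity_sign)
}
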