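#' Remove ocular components by ICA
#'
#' Fits a fast fixed-point ICA decomposition (via [ica::icafast()]) on a
#' 5--40 Hz pseudo-dataset (trials concatenated in time, dimensionality
#' reduced by PCA). Components are flagged as ocular if their broadband time
#' course correlates with the EOG proxy beyond `corr_threshold` in absolute
#' value, or if their sensor topography loads on frontal/ocular channels
#' more than `frontal_ratio` times as strongly as elsewhere. Flagged
#' components are projected out of the original (unfiltered) epochs.
#'
#' The decomposition is fitted on the 5--40 Hz band as in standard ASSR
#' preprocessing, but the correlation criterion is evaluated on broadband
#' component scores, because blink energy lies mostly below 5 Hz.
#'
#' @param epochs An [epoch_set()] with at least 20 channels.
#' @param eog_channel Label or index of the EOG channel; `NULL` uses the
#'   channel tagged `eog`, or, for magnetic modalities without one, the mean
#'   of frontal channels as proxy.
#' @param corr_threshold Absolute correlation threshold (default 0.7).
#' @param frontal_ratio Topography loading ratio threshold (default 4).
#' @param n_components Number of components to estimate (default 30, capped
#'   at channels - 1).
#' @param max_subsample Maximum number of time samples used to fit the
#'   unmixing (full data is always used for projection).
#' @param maxit Maximum fixed-point iterations.
#' @param seed Seed for the ICA initialization.
#' @return List with `epochs` (cleaned), `removed_component_count` and
#'   `removed` (component indices).
#' @export
ica_clean <- function(epochs, eog_channel = NULL, corr_threshold = 0.7,
                      frontal_ratio = 4, n_components = 30,
                      max_subsample = 15000L, maxit = 100L, seed = 1L) {
  nch <- n_channels(epochs)
  if (nch < 20) stop("ICA cleanup requires at least 20 channels for a ",
                     "stable decomposition")
  d <- dim(epochs$data)
  # channels x (trials * samples), trials concatenated chronologically
  flat <- function(arr) {
    matrix(aperm(arr, c(2, 3, 1)), nrow = d[2])
  }
  x_raw <- flat(epochs$data)
  fit_band <- bandpass_filter(epochs, 5, min(40, 0.9 * epochs$sampling_rate_hz / 2))
  x_fit <- flat(fit_band$data)
  regions <- epochs$channel_info$region
  ocular_ch <- which(regions %in% c("eog", "frontal"))
  if (!is.null(eog_channel)) {
    if (is.character(eog_channel)) {
      eog_idx <- match(eog_channel, epochs$channel_info$label)
    } else eog_idx <- eog_channel
  } else if (any(regions == "eog")) {
    eog_idx <- which(regions == "eog")[1]
  } else {
    eog_idx <- NULL
  }
  proxy <- if (!is.null(eog_idx)) {
    x_raw[eog_idx, ]
  } else if (length(ocular_ch)) {
    colMeans(x_raw[ocular_ch, , drop = FALSE])
  } else {
    rep(0, ncol(x_raw))
  }
  nc <- min(n_components, nch - 1)
  idx_fit <- if (ncol(x_fit) > max_subsample) {
    round(seq(1, ncol(x_fit), length.out = max_subsample))
  } else seq_len(ncol(x_fit))
  dec <- with_seed(derive_seed(seed, "ica"), {
    ica::icafast(t(x_fit[, idx_fit]), nc = nc, maxit = maxit, tol = 1e-6)
  })
  M <- dec$M                       # channels x components (mixing)
  unmix <- t(dec$W)                # channels x components: scores = Xc %*% unmix
  scores_raw <- crossprod(x_raw - rowMeans(x_raw), unmix) # samples x comps
  # correlate in the ocular band (< 8 Hz), where blink energy concentrates
  lo <- signal::butter(4, min(8, 0.4 * epochs$sampling_rate_hz / 2) /
                         (epochs$sampling_rate_hz / 2), type = "low")
  proxy_lo <- zp_filter(as.numeric(proxy), lo$b, lo$a)
  scores_lo <- zp_filter(scores_raw, lo$b, lo$a)
  rr <- abs(apply(scores_lo, 2, function(s) {
    if (stats::sd(s) == 0 || stats::sd(proxy_lo) == 0) 0 else
      stats::cor(s, proxy_lo)
  }))
  topo <- apply(M, 2, function(a) {
    num <- mean(abs(a[ocular_ch]))
    den <- mean(abs(a[setdiff(seq_len(nch), ocular_ch)]))
    if (length(ocular_ch) == 0 || den == 0) 0 else num / den
  })
  flagged <- which(rr > corr_threshold | topo > frontal_ratio)
  if (length(flagged)) {
    mu <- rowMeans(x_raw)
    S_f <- crossprod(x_raw - mu, unmix[, flagged, drop = FALSE])
    x_clean <- x_raw - M[, flagged, drop = FALSE] %*% t(S_f)
    arr <- aperm(array(x_clean, dim = c(d[2], d[3], d[1])), c(3, 1, 2))
    epochs <- replace_data(epochs, arr)
  }
  list(epochs = epochs, removed_component_count = length(flagged),
       removed = flagged)
}
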