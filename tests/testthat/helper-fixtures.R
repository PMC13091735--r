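# Fixtures built in code: small layouts, epoch sets and virtual channels.

fixture_layout <- function(n, modality = "SQUID") {
  data.frame(label = sprintf("ch%02d", seq_len(n)),
             x = seq(-0.5, 0.5, length.out = n), y = 0,
             region = "other", axis = "rad", site = seq_len(n),
             stringsAsFactors = FALSE)
}

# epochs of pure signal + iid noise on a handful of channels
fixture_epochs <- function(n_trials = 10, n_channels = 3, fs = 500,
                           signal = NULL, mix = NULL, noise_sd = 1,
                           modality = "SQUID", seed = 1) {
  tax <- seq(-1, 3 - 1 / fs, by = 1 / fs)
  if (is.null(signal)) signal <- sin(2 * pi * 40 * tax) * (tax >= 0 & tax <= 1)
  if (is.null(mix)) mix <- rep(1, n_channels)
  withr::with_seed(seed, {
    dat <- array(rnorm(n_trials * n_channels * length(tax), sd = noise_sd),
                 c(n_trials, n_channels, length(tax)))
    for (i in seq_len(n_trials)) {
      dat[i, , ] <- dat[i, , , drop = TRUE] + outer(mix, signal)
    }
    epoch_set(dat, tax, fs, rep("40Hz", n_trials), seq_len(n_trials),
              fixture_layout(n_channels, modality), modality)
  })
}

# a bare virtual-channel object from a trials x samples matrix
fixture_virtual <- function(data, fs = 500,
                            tax = seq(-1, 3 - 1 / fs, by = 1 / fs)) {
  structure(list(data = data, time_axis_s = tax, sampling_rate_hz = fs,
                 kept_trial_ids = seq_len(nrow(data)),
                 modality = "SQUID", participant_id = "fx"),
            class = "assr_virtual_epochs")
}

# small, fast simulation config used across tests
fixture_sim_config <- function(modality = "OPM", seed = 1, ...) {
  sim_config(modality, seed = seed, sampling_rate_hz = 500,
             n_trials = c("40Hz" = 12L, "20Hz" = 2L, "60Hz" = 2L), ...)
}
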