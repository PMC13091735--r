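#' Study-level configuration
#'
#' Parameters for an end-to-end simulated study: one synthetic session per
#' participant and modality, preprocessing, spatial filtering on the
#' comparable channel subset (and optionally the whole-head set), metric
#' curves over trial counts, and group statistics. Per-participant and
#' per-modality seeds are derived deterministically from `master_seed`.
#'
#' @param n_participants Number of simulated participants (default 23,
#'   a typical cohort for this paradigm).
#' @param modalities Modalities to simulate.
#' @param sim_overrides Named list (by modality, or `all`) of [sim_config()]
#'   argument overrides, e.g. `list(all = list(sampling_rate_hz = 500))`.
#' @param preprocess_params Passed to [run_preprocessing()].
#' @param subset_n Channel-subset size (default 10 sites/electrodes).
#' @param bins Trial-count bins for the curves.
#' @param metrics Metrics to compute (`power_snr`, `itpc_ratio`).
#' @param min_retained_trials Participants with fewer retained trials in any
#'   modality are excluded from group curves (default 70).
#' @param wholehead Also run the whole-channel-set pipeline (for the
#'   subset-versus-whole-head comparison)?
#' @param power_freqs_hz Frequency grid for the power maps inside the
#'   pipeline; the default covers the 40 Hz signal and both noise bands,
#'   which is all the SNR uses.
#' @param itpc_freqs_hz,itpc_times_s Frequency and time grids for ITPC maps
#'   inside the pipeline; defaults cover the 20--30 Hz noise band, the 40 Hz
#'   bin and the stimulation-phase time points that the ITPC ratio uses.
#' @param master_seed Master seed.
#' @param out_dir Output directory, or `NULL` to return results in memory
#'   only.
#' @return Object of class `assr_study_config`.
#' @export
study_config <- function(n_participants = 23,
                         modalities = c("EEG", "OPM", "SQUID"),
                         sim_overrides = list(),
                         preprocess_params = list(),
                         subset_n = 10,
                         bins = c(1, seq(10, 80, by = 10)),
                         metrics = c("power_snr", "itpc_ratio"),
                         min_retained_trials = 70,
                         wholehead = FALSE,
                         power_freqs_hz = seq(20, 48, by = 0.5),
                         itpc_freqs_hz = c(seq(20, 30, by = 0.5), 40),
                         itpc_times_s = seq(0.25, 1, by = 0.25),
                         master_seed = 1L,
                         out_dir = NULL) {
  cfg <- list(n_participants = n_participants, modalities = modalities,
              sim_overrides = sim_overrides,
              preprocess_params = preprocess_params,
              subset_n = subset_n, bins = bins, metrics = metrics,
              min_retained_trials = min_retained_trials,
              wholehead = wholehead, power_freqs_hz = power_freqs_hz,
              itpc_freqs_hz = itpc_freqs_hz, itpc_times_s = itpc_times_s,
              master_seed = as.integer(master_seed), out_dir = out_dir)
  class(cfg) <- "assr_study_config"
  cfg
}

#' Read or write a study config as YAML
#'
#' @param cfg An `assr_study_config`.
#' @param path File path.
#' @return `read_study_config()` returns an `assr_study_config`;
#'   `write_study_config()` returns `path` invisibly.
#' @export
write_study_config <- function(cfg, path) {
  # named atomic vectors inside nested lists lose their names in YAML
  # sequences; store them as maps
  friendly <- function(x) {
    if (is.list(x)) lapply(x, friendly)
    else if (!is.null(names(x))) as.list(x)
    else x
  }
  yaml::write_yaml(friendly(unclass(cfg)), path)
  invisible(path)
}

#' @rdname write_study_config
#' @export
read_study_config <- function(path) {
  do.call(study_config, yaml::read_yaml(path))
}

participant_sim_config <- function(cfg, modality, i) {
  args <- utils::modifyList(
    cfg$sim_overrides$all %||% list(),
    cfg$sim_overrides[[modality]] %||% list())
  if (is.list(args$n_trials)) args$n_trials <- unlist(args$n_trials)
  args$modality <- modality
  args$seed <- derive_seed(cfg$master_seed, modality, i)
  args$participant_id <- sprintf("p%02d", i)
  do.call(sim_config, args)
}

#' Run a full simulated study
#'
#' Executes, per participant and modality: simulate -> preprocess ->
#' channel-subset selection -> canonical-correlation spatial filter ->
#' polarity correction against the group extrema template -> metric curves
#' over chronological trial counts. EEG electrode selection uses the
#' group-average 40 Hz topography and the polarity template uses the grand
#' average over all participants and channels, so preprocessing runs in a
#' first pass (epochs cached on disk) and filtering/metrics in a second.
#' Participants with fewer than `min_retained_trials` retained trials in any
#' modality are excluded from group curves; the group ANOVA additionally
#' requires every bin, i.e. at least `max(bins)` retained trials. All stages
#' are deterministic given the master seed.
#'
#' @param cfg An [study_config()].
#' @return List of class `assr_study`: `results` (long data.frame:
#'   participant, modality, channel_set, metric, bin, value), `group`
#'   (summary per modality/bin from [summarize_group()]), `anova`
#'   (modality x bin rm-ANOVA on the subset power SNR), `pairwise`
#'   (pairwise contrast ANOVAs, `NULL` with fewer than 2 modalities),
#'   `reports` (rejection reports), `manifest`. If `cfg$out_dir` is set,
#'   also writes results.csv, group_summary.csv, anova.json, manifest.json
#'   and (when ggplot2 is available) a group-curve figure.
#' @export
run_study <- function(cfg) {
  stopifnot(inherits(cfg, "assr_study_config"))
  parts <- seq_len(cfg$n_participants)
  cache <- tempfile("assr_study_")
  dir.create(cache)
  on.exit(unlink(cache, recursive = TRUE), add = TRUE)
  reports <- list()
  retained <- matrix(NA_integer_, cfg$n_participants,
                     length(cfg$modalities),
                     dimnames = list(NULL, cfg$modalities))
  topo_sum <- list()   # per modality: running sum of per-channel topography
  ga_sum <- list()     # per modality: running sum of channel-mean averages
  seeds <- expand.grid(participant = parts, modality = cfg$modalities,
                       stringsAsFactors = FALSE)
  seeds$seed <- mapply(function(m, i) derive_seed(cfg$master_seed, m, i),
                       seeds$modality, seeds$participant)
  for (m in cfg$modalities) {
    for (i in parts) {
      scfg <- participant_sim_config(cfg, m, i)
      rec <- simulate_recording(scfg)
      pp <- run_preprocessing(rec, cfg$preprocess_params)
      rm(rec)
      key <- sprintf("%s_%02d", m, i)
      reports[[key]] <- pp$report
      retained[i, m] <- n_trials(pp$epochs)
      tp <- topography_40hz(pp$epochs)
      topo_sum[[m]] <- (topo_sum[[m]] %||% 0) + tp
      ga <- colMeans(apply(pp$epochs$data, c(1, 3), mean))
      ga_sum[[m]] <- (ga_sum[[m]] %||% 0) + ga
      saveRDS(pp$epochs, file.path(cache, paste0(key, ".rds")),
              compress = FALSE)
      rm(pp); gc(FALSE)
    }
  }
  included <- parts[apply(retained >= cfg$min_retained_trials, 1, all)]
  results <- list()
  for (m in cfg$modalities) {
    group_topo <- topo_sum[[m]] / cfg$n_participants
    for (i in parts) {
      key <- sprintf("%s_%02d", m, i)
      ep <- readRDS(file.path(cache, paste0(key, ".rds")))
      template <- build_extrema_template(ga_sum[[m]] / cfg$n_participants,
                                         ep$time_axis_s)
      sets <- list(subset = select_channel_subset(ep, cfg$subset_n,
                                                  topography = group_topo))
      if (isTRUE(cfg$wholehead)) sets$wholehead <- ep
      for (set_name in names(sets)) {
        eps <- sets[[set_name]]
        spec <- fit_cca_filter(eps)
        virt <- fix_polarity(apply_spatial_filter(eps, spec), template)
        for (metric in cfg$metrics) {
          bins <- cfg$bins
          if (metric == "itpc_ratio") bins <- bins[bins >= 2]
          bins <- bins[bins <= n_trials(eps)]
          if (length(bins) == 0) next
          cu <- if (metric == "itpc_ratio") {
            trial_count_curve(virt, bins, metric,
                              freqs_hz = cfg$itpc_freqs_hz,
                              times_s = cfg$itpc_times_s)
          } else {
            trial_count_curve(virt, bins, metric,
                              freqs_hz = cfg$power_freqs_hz)
          }
          results[[length(results) + 1]] <- data.frame(
            participant = i, modality = m, channel_set = set_name,
            metric = metric, bin = cu$bins, value = cu$values,
            retained = n_trials(eps), stringsAsFactors = FALSE)
        }
      }
      rm(ep, sets); gc(FALSE)
    }
  }
  results <- do.call(rbind, results)
  group_in <- results[results$participant %in% included &
                        results$channel_set == "subset", ]
  group <- do.call(rbind, lapply(split(group_in, group_in$metric),
                                 function(g) {
    s <- summarize_group(g[, c("participant", "modality", "bin", "value")])
    s$metric <- g$metric[1]
    s
  }))
  rownames(group) <- NULL
  anova_tab <- pairwise <- NULL
  full <- results[results$channel_set == "subset" &
                    results$metric == "power_snr" &
                    results$participant %in% included &
                    results$retained >= max(cfg$bins), ]
  full_parts <- names(which(table(full$participant) == length(unique(
    paste(full$modality, full$bin)))))
  full <- full[full$participant %in% as.integer(full_parts), ]
  if (length(unique(full$participant)) >= 3) {
    if (length(unique(full$modality)) >= 2) {
      anova_tab <- rm_anova_two_way(full, dv = "value",
                                    subject = "participant",
                                    within = c("modality", "bin"))
      pairwise <- pairwise_contrast_anovas(full)
    } else {
      anova_tab <- rm_anova_two_way(full, dv = "value",
                                    subject = "participant", within = "bin")
      message("single modality: skipping modality contrasts")
    }
  }
  manifest <- list(
    package_version = as.character(utils::packageVersion("assr")),
    master_seed = cfg$master_seed,
    config_hash = rlang::hash(cfg),
    seeds = seeds,
    n_participants = cfg$n_participants,
    participants_in_group = included,
    retained_trials = as.data.frame(retained))
  out <- structure(list(results = results, group = group, anova = anova_tab,
                        pairwise = pairwise, reports = reports,
                        manifest = manifest),
                   class = "assr_study")
  if (!is.null(cfg$out_dir)) write_study_outputs(out, cfg)
  out
}

write_study_outputs <- function(out, cfg) {
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(out$results, file.path(cfg$out_dir, "results.csv"),
                   row.names = FALSE)
  utils::write.csv(out$group, file.path(cfg$out_dir, "group_summary.csv"),
                   row.names = FALSE)
  if (!is.null(out$anova)) {
    jsonlite::write_json(list(anova = as.data.frame(out$anova)),
                         file.path(cfg$out_dir, "anova.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  jsonlite::write_json(out$manifest, file.path(cfg$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  for (key in names(out$reports)) {
    dir.create(file.path(cfg$out_dir, key), showWarnings = FALSE)
    write_rejection_report(out$reports[[key]],
                           file.path(cfg$out_dir, key, "rejection.json"))
  }
  if (requireNamespace("ggplot2", quietly = TRUE)) {
    g <- out$group
    pl <- ggplot2::ggplot(g, ggplot2::aes(x = bin, y = mean,
                                          color = modality,
                                          fill = modality)) +
      ggplot2::geom_ribbon(ggplot2::aes(ymin = mean - sem, ymax = mean + sem),
                           alpha = 0.25, color = NA) +
      ggplot2::geom_line() + ggplot2::geom_point() +
      ggplot2::facet_wrap(~metric, scales = "free_y") +
      ggplot2::labs(x = "trials (chronological)", y = "linear ratio") +
      ggplot2::theme_minimal()
    try(ggplot2::ggsave(file.path(cfg$out_dir, "group_curves.png"), pl,
                        width = 8, height = 4, dpi = 120), silent = TRUE)
  }
  invisible(NULL)
}

#' @export
print.assr_study <- function(x, ...) {
  cat(sprintf("<assr_study> %d participants (%d in group analysis), modalities: %s\n",
              x$manifest$n_participants,
              length(x$manifest$participants_in_group),
              paste(unique(x$results$modality), collapse = ", ")))
  invisible(x)
}

#' Compare channel-subset and whole-head SNR
#'
#' Runs the metric pipeline twice per participant -- once on the comparable
#' channel subset and once on all channels entering the spatial filter --
#' and returns paired values for the subset-versus-whole-head
#' repeated-measures comparison, plus a 2 x bins rm-ANOVA per modality.
#'
#' @param cfg An [study_config()]; `wholehead` is forced on.
#' @return List with `paired` (long data.frame), `anovas` (per modality,
#'   channel_set x bin rm-ANOVA on power SNR) and `study` (the full
#'   `assr_study`).
#' @export
compare_subset_vs_wholehead <- function(cfg) {
  cfg$wholehead <- TRUE
  st <- run_study(cfg)
  paired <- st$results[st$results$metric == "power_snr" &
                         st$results$participant %in%
                         st$manifest$participants_in_group, ]
  anovas <- list()
  for (m in unique(paired$modality)) {
    sub <- paired[paired$modality == m &
                    paired$retained >= max(cfg$bins), ]
    keep <- names(which(table(sub$participant) ==
                          2 * length(unique(sub$bin))))
    sub <- sub[sub$participant %in% as.integer(keep), ]
    if (length(unique(sub$participant)) >= 3) {
      anovas[[m]] <- rm_anova_two_way(sub, dv = "value",
                                      subject = "participant",
                                      within = c("channel_set", "bin"))
    }
  }
  list(paired = paired, anovas = anovas, study = st)
}
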