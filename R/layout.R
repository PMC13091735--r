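#' Schematic sensor layout for a simulated modality
#'
#' Places sensors on a schematic 2-D head (unit disk, nose towards +y) and
#' tags each channel with a nominal scalp region. EEG uses 56 roughly
#' equidistant scalp electrodes plus one EOG electrode near the eyes; SQUID
#' uses 124 gradiometers covering the whole head with 5 left + 5 right
#' channels tagged `temporal`; OPM uses `n_sites` dual-axis sensors over the
#' left and right temporal regions (two channels per site, axes `rad` and
#' `tan`).
#'
#' @param config An [sim_config()] object (or a modality string, in which
#'   case defaults are used).
#' @return A data.frame with columns `label`, `x`, `y`, `region`
#'   (`frontal`, `frontocentral`, `temporal`, `other`, `eog`), `axis`
#'   (`rad`/`tan` for OPM, `rad` otherwise) and `site`.
#' @export
sensor_layout <- function(config) {
  if (is.character(config)) config <- sim_config(config)
  modality <- config$modality
  if (modality == "EEG") {
    pos <- disk_grid(c(1, 7, 12, 16, 20), c(0, 0.25, 0.5, 0.72, 0.92))
    region <- tag_regions(pos)
    lay <- data.frame(
      label = sprintf("EEG%03d", seq_len(nrow(pos))),
      x = pos[, 1], y = pos[, 2], region = region,
      axis = "rad", site = seq_len(nrow(pos)),
      stringsAsFactors = FALSE)
    lay <- rbind(lay, data.frame(label = "EOG", x = 0.25, y = 1.05,
                                 region = "eog", axis = "rad",
                                 site = nrow(pos) + 1L))
  } else if (modality == "SQUID") {
    pos <- disk_grid(c(1, 8, 14, 20, 26, 25, 30),
                     c(0, 0.18, 0.36, 0.54, 0.72, 0.87, 1.0))
    region <- tag_regions(pos)
    # tag as temporal the gradiometers in positions matching the canonical
    # 5-site OPM arcs above each ear, plus anything within 0.3 of the arc
    region[region == "temporal"] <- "other"
    for (sgn in c(-1, 1)) {
      ref <- temporal_arc(5, sgn)
      for (r in seq_len(nrow(ref))) {
        d <- sqrt((pos[, 1] - ref[r, 1])^2 + (pos[, 2] - ref[r, 2])^2)
        region[d < 0.3 | rank(d, ties.method = "first") == 1] <- "temporal"
      }
    }
    lay <- data.frame(
      label = sprintf("MEG%03d", seq_len(nrow(pos))),
      x = pos[, 1], y = pos[, 2], region = region,
      axis = "rad", site = seq_len(nrow(pos)),
      stringsAsFactors = FALSE)
  } else { # OPM
    n <- config$n_sites
    n_left <- ceiling(n / 2)
    n_right <- n - n_left
    pos_l <- temporal_arc(n_left, -1)
    pos_r <- temporal_arc(n_right, 1)
    px <- c(pos_l[, 1], pos_r[, 1])
    py <- c(pos_l[, 2], pos_r[, 2])
    lay <- do.call(rbind, lapply(seq_len(n), function(i) {
      data.frame(label = sprintf("OPM%02d%s", i, c("y", "z")),
                 x = px[i], y = py[i], region = "temporal",
                 axis = c("rad", "tan"), site = i,
                 stringsAsFactors = FALSE)
    }))
  }
  rownames(lay) <- NULL
  lay
}

# arc of sensor sites over one temporal region (side -1 = left, +1 = right);
# the 5-site arc is the canonical "5 lateral positions above the ear" that
# OPM placement uses and to which SQUID gradiometers are position-matched
temporal_arc <- function(k, side) {
  ang <- if (side < 0) seq(140, 220, length.out = k) * pi / 180 else
    seq(40, -40, length.out = k) * pi / 180
  cbind(0.88 * cos(ang), 0.88 * sin(ang))
}

# concentric rings of sensors on the unit disk
disk_grid <- function(counts, radii) {
  pos <- matrix(0, 0, 2)
  for (i in seq_along(counts)) {
    k <- counts[i]
    if (radii[i] == 0) {
      pos <- rbind(pos, c(0, 0))
    } else {
      ang <- seq(0, 2 * pi, length.out = k + 1)[-(k + 1)] + pi / (2 * k)
      pos <- rbind(pos, cbind(radii[i] * sin(ang), radii[i] * cos(ang)))
    }
  }
  pos
}

tag_regions <- function(pos) {
  region <- rep("other", nrow(pos))
  region[pos[, 2] > 0.7] <- "frontal"
  region[sqrt(pos[, 1]^2 + (pos[, 2] - 0.35)^2) < 0.45] <- "frontocentral"
  for (sgn in c(-1, 1)) {
    d <- sqrt((pos[, 1] - sgn * 0.9)^2 + pos[, 2]^2)
    region[d < 0.35] <- "temporal"
  }
  region
}

# gaussian spatial kernel on the schematic head
gauss_w <- function(pos, center, width) {
  exp(-((pos[, 1] - center[1])^2 + (pos[, 2] - center[2])^2) / (2 * width^2))
}

# fixed per-modality forward pattern of the auditory steady-state source,
# normalized to peak gain 1 (before evoked amplitude and OPM factor):
# bilateral dipolar field for the magnetic modalities, broad smeared
# fronto-central potential for EEG
forward_pattern <- function(layout, modality, second_axis_gain = 0.6) {
  pos <- cbind(layout$x, layout$y)
  if (modality == "EEG") {
    w <- gauss_w(pos, c(0, 0.35), 0.55)
    w[layout$region == "eog"] <- 0
  } else {
    dip <- function(side) {
      gauss_w(pos, c(side * 0.78, 0.30), 0.35) -
        gauss_w(pos, c(side * 0.78, -0.25), 0.35)
    }
    w <- dip(-1) + dip(1)
    if (any(layout$axis == "tan")) {
      tanp <- gauss_w(pos, c(-0.78, 0.05), 0.4) + gauss_w(pos, c(0.78, 0.05), 0.4)
      tan_sel <- layout$axis == "tan"
      w[tan_sel] <- tanp[tan_sel] / max(abs(tanp)) * second_axis_gain *
        max(abs(w[!tan_sel]))
    }
  }
  w / max(abs(w))
}

# blink (ocular) loading: distance to the eyes, EOG channel loads fully
blink_pattern <- function(layout) {
  w <- gauss_w(cbind(layout$x, layout$y), c(0, 1.0), 0.35)
  w[layout$region == "eog"] <- 1
  w
}
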