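#' Greenhouse-Geisser epsilon
#'
#' Sphericity-violation correction factor computed from the eigenvalues of
#' the double-centered covariance matrix of the `k` within-subject levels:
#' `epsilon = (sum lambda)^2 / ((k - 1) * sum lambda^2)`, clamped to
#' `[1/(k-1), 1]`. Equals 1 under compound symmetry (sphericity) and its
#' lower bound `1/(k-1)` for a rank-1 covariance (maximal violation).
#'
#' @param covariance_of_levels Symmetric k x k covariance matrix of the
#'   level measurements across subjects.
#' @return Scalar epsilon.
#' @export
greenhouse_geisser_epsilon <- function(covariance_of_levels) {
  s <- as.matrix(covariance_of_levels)
  if (nrow(s) != ncol(s) || max(abs(s - t(s))) > 1e-8 * max(1, max(abs(s)))) {
    stop("covariance matrix must be symmetric")
  }
  k <- nrow(s)
  if (k < 2) stop("at least 2 levels required")
  cmat <- diag(k) - 1 / k
  sc <- cmat %*% s %*% cmat
  lam <- eigen((sc + t(sc)) / 2, symmetric = TRUE, only.values = TRUE)$values
  lam <- lam[lam > max(lam) * 1e-12]
  eps <- sum(lam)^2 / ((k - 1) * sum(lam^2))
  min(1, max(1 / (k - 1), eps))
}

#' Mauchly's test of sphericity
#'
#' Tests whether the covariance of within-subject level differences is
#' spherical. `W` is the ratio of the determinant to the scaled trace of the
#' orthonormalized level-difference covariance; the p-value uses the
#' standard chi-square approximation. With `k = 2` levels sphericity holds
#' trivially (`W = 1`, `p = 1`).
#'
#' @param level_data Numeric matrix, subjects x levels.
#' @return List with `W` and `p`.
#' @export
mauchly_test <- function(level_data) {
  x <- as.matrix(level_data)
  n <- nrow(x)
  k <- ncol(x)
  if (k < 2) stop("at least 2 levels required")
  if (k == 2) return(list(W = 1, p = 1))
  if (n <= k - 1) {
    stop("Mauchly's test needs more subjects (", n, ") than contrasts (",
         k - 1, ")")
  }
  cm <- orthonormal_contrasts(k)
  s <- cm %*% stats::cov(x) %*% t(cm)
  p <- k - 1
  W <- det(s) / (sum(diag(s)) / p)^p
  f <- n - 1
  d <- 1 - (2 * p^2 + p + 2) / (6 * p * f)
  chi <- -f * d * log(W)
  df <- p * (p + 1) / 2 - 1
  list(W = W, p = stats::pchisq(chi, df, lower.tail = FALSE))
}

# rows are k-1 orthonormal contrasts of k levels (Helmert, normalized)
orthonormal_contrasts <- function(k) {
  cm <- stats::contr.helmert(k)
  t(cm) / sqrt(colSums(cm^2))
}

#' Partial eta squared from F and degrees of freedom
#'
#' Effect size `eta_p^2 = SS_effect / (SS_effect + SS_residual)`, recovered
#' from an F statistic via the identity
#' `eta_p^2 = F * df_effect / (F * df_effect + df_residual)`, which holds
#' for within-subject effects whether the dfs are raw or sphericity-corrected.
#'
#' @param f F statistic (>= 0).
#' @param df_effect,df_residual Degrees of freedom (> 0).
#' @return Scalar in [0, 1].
#' @export
eta_p_sq_from_f <- function(f, df_effect, df_residual) {
  if (df_effect <= 0 || df_residual <= 0) stop("degrees of freedom must be positive")
  if (f < 0) stop("F must be non-negative")
  f * df_effect / (f * df_effect + df_residual)
}

#' Two-way repeated-measures ANOVA
#'
#' Fully within-subject two-factor ANOVA with the classical sum-of-squares
#' decomposition (each effect tested against its own effect x subject
#' interaction). For every effect, Mauchly's test is run on the effect's
#' orthonormal contrast scores (when the subject count allows it) and, when
#' sphericity is rejected at `gg_alpha` -- or untestable -- the
#' Greenhouse-Geisser epsilon multiplies both degrees of freedom and the
#' p-value is recomputed. Partial eta squared is reported from the SS
#' definition `SS_effect / (SS_effect + SS_residual)`.
#'
#' @param data Long data.frame.
#' @param dv,subject Column names of the response and subject id.
#' @param within Character vector of one or two within-factor column names.
#' @param gg One of `"auto"` (correct when Mauchly p < `gg_alpha` or the
#'   test is untestable), `"always"`, `"never"`.
#' @param gg_alpha Mauchly significance threshold (default 0.05).
#' @return Object of class `assr_rm_anova`: a data.frame with one row per
#'   effect (`effect`, `SS_effect`, `SS_error`, `F`, `df_effect`,
#'   `df_residual`, `df_effect_corr`, `df_residual_corr`, `p_uncorrected`,
#'   `p`, `epsilon_gg`, `mauchly_W`, `mauchly_p`, `corrected`, `eta_p_sq`).
#' @export
rm_anova_two_way <- function(data, dv = "value", subject = "participant",
                             within = c("modality", "bin"),
                             gg = c("auto", "always", "never"),
                             gg_alpha = 0.05) {
  gg <- match.arg(gg)
  stopifnot(length(within) %in% c(1, 2))
  subj <- factor(data[[subject]])
  fa <- factor(data[[within[1]]])
  fb <- if (length(within) == 2) factor(data[[within[2]]]) else
    factor(rep(1, nrow(data)))
  y <- data[[dv]]
  n <- nlevels(subj); a <- nlevels(fa); b <- nlevels(fb)
  if (a < 2) stop("first within factor needs at least 2 levels")
  if (n < 3) stop("at least 3 subjects required")
  if (any(table(subj, fa, fb) != 1)) {
    stop("design must be complete and balanced: exactly one value per ",
         "subject x cell")
  }
  cube <- array(NA_real_, c(n, a, b))
  cube[cbind(as.integer(subj), as.integer(fa), as.integer(fb))] <- y
  gm <- mean(cube)
  m_s <- apply(cube, 1, mean)
  m_a <- apply(cube, 2, mean)
  m_b <- apply(cube, 3, mean)
  m_sa <- apply(cube, c(1, 2), mean)
  m_sb <- apply(cube, c(1, 3), mean)
  m_ab <- apply(cube, c(2, 3), mean)
  ss_a <- n * b * sum((m_a - gm)^2)
  res_sa <- m_sa - outer(m_s, rep(1, a)) - outer(rep(1, n), m_a) + gm
  ss_as <- b * sum(res_sa^2)
  effects <- list(list(name = within[1], ss = ss_a, ss_err = ss_as,
                       df1 = a - 1, df2 = (a - 1) * (n - 1),
                       scores = effect_scores(cube, "a")))
  if (b > 1) {
    ss_b <- n * a * sum((m_b - gm)^2)
    res_sb <- m_sb - outer(m_s, rep(1, b)) - outer(rep(1, n), m_b) + gm
    ss_bs <- a * sum(res_sb^2)
    ss_ab <- n * sum((m_ab - outer(m_a, rep(1, b)) -
                        outer(rep(1, a), m_b) + gm)^2)
    res3 <- cube
    for (i in seq_len(n)) for (j in seq_len(a)) for (l in seq_len(b)) {
      res3[i, j, l] <- cube[i, j, l] - m_sa[i, j] - m_sb[i, l] -
        m_ab[j, l] + m_s[i] + m_a[j] + m_b[l] - gm
    }
    ss_abs <- sum(res3^2)
    effects <- c(effects, list(
      list(name = within[2], ss = ss_b, ss_err = ss_bs,
           df1 = b - 1, df2 = (b - 1) * (n - 1),
           scores = effect_scores(cube, "b")),
      list(name = paste(within, collapse = ":"), ss = ss_ab, ss_err = ss_abs,
           df1 = (a - 1) * (b - 1), df2 = (a - 1) * (b - 1) * (n - 1),
           scores = effect_scores(cube, "ab"))))
  }
  rows <- lapply(effects, function(e) {
    ms_eff <- e$ss / e$df1
    ms_err <- e$ss_err / e$df2
    fval <- if (ms_err > 0) ms_eff / ms_err else 0
    p_unc <- stats::pf(fval, e$df1, e$df2, lower.tail = FALSE)
    eps <- if (e$df1 >= 2) {
      greenhouse_geisser_epsilon(stats::cov(e$scores) |> decontrast())
    } else 1
    mw <- mp <- NA_real_
    testable <- ncol(e$scores) >= 2 && nrow(e$scores) > ncol(e$scores)
    if (ncol(e$scores) < 2) { mw <- 1; mp <- 1 } else if (testable) {
      # scores are already orthonormal contrasts; test their covariance
      s <- stats::cov(e$scores)
      p <- ncol(s)
      mw <- det(s) / (sum(diag(s)) / p)^p
      f <- nrow(e$scores) - 1
      d <- 1 - (2 * p^2 + p + 2) / (6 * p * f)
      mp <- stats::pchisq(-f * d * log(mw), p * (p + 1) / 2 - 1,
                          lower.tail = FALSE)
    }
    correct <- switch(gg, always = e$df1 >= 2,
                      never = FALSE,
                      auto = e$df1 >= 2 && (is.na(mp) || mp < gg_alpha))
    df1c <- if (correct) eps * e$df1 else e$df1
    df2c <- if (correct) eps * e$df2 else e$df2
    pval <- stats::pf(fval, df1c, df2c, lower.tail = FALSE)
    data.frame(effect = e$name, SS_effect = e$ss, SS_error = e$ss_err,
               F = fval, df_effect = e$df1, df_residual = e$df2,
               df_effect_corr = df1c, df_residual_corr = df2c,
               p_uncorrected = p_unc, p = pval, epsilon_gg = eps,
               mauchly_W = mw, mauchly_p = mp, corrected = correct,
               eta_p_sq = if (e$ss + e$ss_err > 0)
                 e$ss / (e$ss + e$ss_err) else 0,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "n_subjects") <- n
  class(out) <- c("assr_rm_anova", "data.frame")
  out
}

# subjects x contrast scores for an effect of the n x a x b cube
effect_scores <- function(cube, which) {
  n <- dim(cube)[1]; a <- dim(cube)[2]; b <- dim(cube)[3]
  if (which == "a") {
    m <- apply(cube, c(1, 2), mean)
    return(m %*% t(orthonormal_contrasts(a)))
  }
  if (which == "b") {
    m <- apply(cube, c(1, 3), mean)
    return(m %*% t(orthonormal_contrasts(b)))
  }
  ca <- orthonormal_contrasts(a)
  cb <- orthonormal_contrasts(b)
  flat <- matrix(cube, n, a * b)    # column order: a fastest, then b
  cc <- kronecker(cb, ca)           # rows: (a-1)(b-1) contrasts of a*b cells
  flat %*% t(cc)
}

# rebuild a level-space covariance from contrast-space so the documented
# epsilon formula (double-centered level covariance) applies unchanged
decontrast <- function(s_contrast) {
  p <- ncol(s_contrast)
  cm <- orthonormal_contrasts(p + 1)
  t(cm) %*% s_contrast %*% cm
}

#' @export
print.assr_rm_anova <- function(x, ...) {
  df <- as.data.frame(x)
  cat(sprintf("Repeated-measures ANOVA (n = %d subjects)\n",
              attr(x, "n_subjects")))
  for (i in seq_len(nrow(df))) {
    r <- df[i, ]
    cat(sprintf("  %-18s F(%.2f, %.2f) = %.2f, p = %.4g%s, eta_p^2 = %.2f\n",
                r$effect, r$df_effect_corr, r$df_residual_corr, r$F, r$p,
                if (r$corrected) " (GG-corrected)" else "", r$eta_p_sq))
  }
  invisible(x)
}

#' Tukey HSD post hoc contrasts
#'
#' All pairwise level contrasts with studentized-range adjusted p-values,
#' using the supplied residual mean square and degrees of freedom as the
#' error term (for a within design: the effect x subject MS of the effect
#' being decomposed).
#'
#' @param level_means Named numeric vector of level means.
#' @param ms_residual Residual mean square of the error term.
#' @param df_residual Its degrees of freedom.
#' @param n_per_level Number of observations per level mean.
#' @param alpha Significance level for the `significant` flag.
#' @return Data.frame with `level_1`, `level_2`, `difference`, `p_adj`,
#'   `significant`.
#' @export
tukey_hsd <- function(level_means, ms_residual, df_residual, n_per_level,
                      alpha = 0.05) {
  k <- length(level_means)
  if (k < 2) stop("at least 2 levels required")
  if (df_residual <= 0) stop("degrees of freedom must be positive")
  nm <- names(level_means) %||% as.character(seq_len(k))
  se <- sqrt(ms_residual / n_per_level)
  pairs <- utils::combn(k, 2)
  out <- apply(pairs, 2, function(ij) {
    d <- level_means[ij[1]] - level_means[ij[2]]
    q <- abs(d) / se
    p <- stats::ptukey(q, k, df_residual, lower.tail = FALSE)
    data.frame(level_1 = nm[ij[1]], level_2 = nm[ij[2]],
               difference = unname(d), p_adj = p,
               significant = p < alpha, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Pairwise two-factor contrast ANOVAs
#'
#' One 2 x B repeated-measures ANOVA per pair of levels of `pair_factor`
#' (e.g., per modality pair), as used to place per-bin significance markers
#' under group trial-count curves. Additionally reports, per bin, a Tukey
#' contrast of the two levels using the modality x subject error term of a
#' one-way ANOVA at that bin.
#'
#' @param data Long data.frame with the same layout as [rm_anova_two_way()].
#' @param dv,subject Column names.
#' @param pair_factor Factor whose level pairs are contrasted.
#' @param other_factor Second within factor (e.g., trial-count bin).
#' @param alpha Significance level for the per-bin flags.
#' @return List with `anovas` (named list of `assr_rm_anova`) and `per_bin`
#'   (data.frame `pair`, `bin`, `difference`, `p_adj`, `significant`).
#' @export
pairwise_contrast_anovas <- function(data, dv = "value",
                                     subject = "participant",
                                     pair_factor = "modality",
                                     other_factor = "bin", alpha = 0.05) {
  levs <- unique(as.character(data[[pair_factor]]))
  if (length(levs) < 2) stop("pair factor needs at least 2 levels")
  prs <- utils::combn(levs, 2, simplify = FALSE)
  anovas <- list()
  per_bin <- list()
  for (pr in prs) {
    key <- paste(pr, collapse = "_vs_")
    sub <- data[data[[pair_factor]] %in% pr, , drop = FALSE]
    anovas[[key]] <- rm_anova_two_way(sub, dv, subject,
                                      within = c(pair_factor, other_factor))
    for (b in unique(sub[[other_factor]])) {
      slice <- sub[sub[[other_factor]] == b, , drop = FALSE]
      one <- rm_anova_two_way(slice, dv, subject, within = pair_factor)
      means <- tapply(slice[[dv]], as.character(slice[[pair_factor]]), mean)
      tk <- tukey_hsd(means, one$SS_error / one$df_residual,
                      one$df_residual,
                      length(unique(slice[[subject]])), alpha)
      per_bin[[length(per_bin) + 1]] <-
        data.frame(pair = key, bin = b, difference = tk$difference,
                   p_adj = tk$p_adj, significant = tk$significant,
                   stringsAsFactors = FALSE)
    }
  }
  list(anovas = anovas, per_bin = do.call(rbind, per_bin))
}
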