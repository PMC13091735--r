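test_that("rm-ANOVA reproduces the explicit sum-of-squares oracle exactly", {
  cube <- array(c(3, 5, 2, 8, 4, 6, 7, 1, 9, 2, 5, 6,
                  4, 4, 3, 7, 5, 5, 8, 2, 8, 3, 4, 7), c(4, 3, 2))
  tab <- rm_anova_two_way(grid_to_df(cube), within = c("A", "B"),
                          subject = "participant", gg = "never")
  ss <- oracle_ss(cube)
  expect_equal(tab$SS_effect, c(ss$A, ss$B, ss$AB), tolerance = 1e-10)
  expect_equal(tab$SS_error, c(ss$AS, ss$BS, ss$ABS), tolerance = 1e-10)
  expect_equal(tab$F, c((ss$A / 2) / (ss$AS / 6),
                        (ss$B / 1) / (ss$BS / 3),
                        (ss$AB / 2) / (ss$ABS / 6)), tolerance = 1e-10)
  expect_equal(tab$eta_p_sq,
               c(ss$A / (ss$A + ss$AS), ss$B / (ss$B + ss$BS),
                 ss$AB / (ss$AB + ss$ABS)), tolerance = 1e-10)
})

test_that("rm-ANOVA F statistics agree with stats::aov on random grids", {
  for (s in 1:3) {
    cube <- withr::with_seed(s, array(rnorm(6 * 3 * 4), c(6, 3, 4)))
    df <- grid_to_df(cube)
    tab <- rm_anova_two_way(df, within = c("A", "B"),
                            subject = "participant", gg = "never")
    fit <- summary(aov(value ~ A * B + Error(participant / (A * B)),
                       data = df))
    expect_equal(tab$F[1], fit[["Error: participant:A"]][[1]]["A", "F value"],
                 tolerance = 1e-10)
    expect_equal(tab$F[2], fit[["Error: participant:B"]][[1]]["B", "F value"],
                 tolerance = 1e-10)
    expect_equal(tab$F[3],
                 fit[["Error: participant:A:B"]][[1]]["A:B", "F value"],
                 tolerance = 1e-10)
  }
})

test_that("degenerate and guarded ANOVA inputs behave as documented", {
  cube <- array(rep(1:4, 6), c(4, 3, 2))   # no level differences
  tab <- rm_anova_two_way(grid_to_df(cube), within = c("A", "B"),
                          subject = "participant")
  expect_equal(tab$F, c(0, 0, 0))
  expect_equal(tab$eta_p_sq, c(0, 0, 0))
  df <- grid_to_df(array(rnorm(24), c(4, 3, 2)))
  expect_error(rm_anova_two_way(df[-1, ], within = c("A", "B"),
                                subject = "participant"), "balanced")
  two <- df[df$participant %in% c(1, 2), ]
  expect_error(rm_anova_two_way(two, within = c("A", "B"),
                                subject = "participant"), "3 subjects")
})

test_that("Greenhouse-Geisser epsilon matches its eigenvalue definition", {
  cs <- diag(3) * 0.5 + 0.5   # compound symmetry
  expect_equal(greenhouse_geisser_epsilon(cs), 1)
  v <- c(1, -2, 1)
  expect_equal(greenhouse_geisser_epsilon(outer(v, v)), 0.5)
  S <- withr::with_seed(4, crossprod(matrix(rnorm(40), 10, 4)))
  k <- 4
  cmat <- diag(k) - 1 / k
  sc <- cmat %*% S %*% cmat
  lam <- eigen(sc, symmetric = TRUE, only.values = TRUE)$values[1:(k - 1)]
  expect_equal(greenhouse_geisser_epsilon(S),
               sum(lam)^2 / ((k - 1) * sum(lam^2)), tolerance = 1e-12)
  expect_error(greenhouse_geisser_epsilon(matrix(1:4, 2)), "symmetric")
})

test_that("epsilon concentrates near 1 for spherical data", {
  # the estimator is consistent but biased low at moderate n; at n = 50 the
  # simulated mean is ~0.96 (oracle-computed), converging to 1 by n = 500
  eps <- vapply(1:20, function(s) {
    x <- withr::with_seed(600 + s, matrix(rnorm(50 * 3), 50, 3))
    greenhouse_geisser_epsilon(cov(x))
  }, numeric(1))
  expect_true(all(eps > 0.8))
  expect_gt(mean(eps), 0.94)
  eps_big <- vapply(1:5, function(s) {
    x <- withr::with_seed(700 + s, matrix(rnorm(500 * 3), 500, 3))
    greenhouse_geisser_epsilon(cov(x))
  }, numeric(1))
  expect_true(all(eps_big > 0.98))
})

test_that("Mauchly's test matches the reference implementation and is calibrated", {
  x <- withr::with_seed(8, matrix(rnorm(20 * 4), 20, 4) %*%
                          matrix(rnorm(16), 4, 4))
  mt <- mauchly_test(x)
  ref <- mauchly.test(lm(x ~ 1), X = ~1)
  expect_equal(mt$W, unname(ref$statistic), tolerance = 1e-10)
  expect_equal(mt$p, ref$p.value, tolerance = 0.15)
  expect_equal(mauchly_test(matrix(rnorm(20), 10, 2)), list(W = 1, p = 1))
  expect_error(mauchly_test(matrix(rnorm(8), 2, 4)), "more subjects")
  # type-I calibration under sphericity
  rej <- vapply(1:500, function(s) {
    mauchly_test(withr::with_seed(1000 + s,
                                  matrix(rnorm(100 * 3), 100, 3)))$p < 0.05
  }, logical(1))
  expect_gte(mean(rej), 0.02)
  expect_lte(mean(rej), 0.10)
  # power under strong heteroscedasticity
  pow <- vapply(1:200, function(s) {
    x <- withr::with_seed(2000 + s,
                          cbind(rnorm(50, sd = sqrt(10)), rnorm(50), rnorm(50)))
    mauchly_test(x)$p < 0.05
  }, logical(1))
  expect_gt(mean(pow), 0.5)
})

test_that("Tukey HSD matches the paired t-test for two levels", {
  y1 <- withr::with_seed(3, rnorm(12))
  y2 <- y1 + withr::with_seed(4, rnorm(12, 0.4))
  dd <- data.frame(participant = factor(rep(1:12, 2)),
                   A = factor(rep(1:2, each = 12)), value = c(y1, y2))
  one <- rm_anova_two_way(dd, within = "A", subject = "participant")
  tk <- tukey_hsd(tapply(dd$value, dd$A, mean),
                  one$SS_error / one$df_residual, one$df_residual, 12)
  expect_equal(tk$p_adj, t.test(y1, y2, paired = TRUE)$p.value,
               tolerance = 1e-6)
})

test_that("Tukey HSD separates a far level and never flags identical means", {
  tk0 <- tukey_hsd(c(a = 1, b = 1, c = 1), ms_residual = 1,
                   df_residual = 20, n_per_level = 10)
  expect_true(all(tk0$p_adj >= 0.999))
  tk <- tukey_hsd(c(a = 0, b = 0.1, c = 5), ms_residual = 0.5,
                  df_residual = 20, n_per_level = 10)
  expect_lt(tk$p_adj[tk$level_1 == "a" & tk$level_2 == "c"], 0.001)
  expect_gt(tk$p_adj[tk$level_1 == "a" & tk$level_2 == "b"], 0.05)
  expect_error(tukey_hsd(c(1, 2), 1, -3, 5), "positive")
})

test_that("pairwise contrast ANOVAs cover all modality pairs", {
  cube <- withr::with_seed(10, array(rnorm(8 * 3 * 4), c(8, 3, 4)))
  df <- grid_to_df(cube)
  names(df)[2:3] <- c("modality", "bin")
  levels(df$modality) <- c("EEG", "OPM", "SQUID")
  pw <- pairwise_contrast_anovas(df)
  expect_length(pw$anovas, 3)
  expect_setequal(names(pw$anovas),
                  c("EEG_vs_OPM", "EEG_vs_SQUID", "OPM_vs_SQUID"))
  expect_equal(nrow(pw$per_bin), 3 * 4)
  # identical data in a pair: modality effect vanishes
  df2 <- df[df$modality %in% c("EEG", "OPM"), ]
  df2$value[df2$modality == "OPM"] <- df2$value[df2$modality == "EEG"]
  tab <- rm_anova_two_way(df2, within = c("modality", "bin"),
                          subject = "participant")
  expect_lt(tab$F[1], 1e-10)
})

test_that("a one-SD modality shift is detected in most simulated studies", {
  hits <- vapply(1:20, function(s) {
    cube <- withr::with_seed(3000 + s, array(rnorm(21 * 2 * 4), c(21, 2, 4)))
    cube[, 2, ] <- cube[, 2, ] + 1
    df <- grid_to_df(cube)
    names(df)[2:3] <- c("modality", "bin")
    tab <- rm_anova_two_way(df, within = c("modality", "bin"),
                            subject = "participant")
    tab$p[1] < 0.05
  }, logical(1))
  expect_gte(mean(hits), 0.9)
})

test_that("partial eta squared reproduces reported effect sizes and identities", {
  expect_equal(round(eta_p_sq_from_f(11.49, 2, 44), 2), 0.34)
  expect_equal(round(eta_p_sq_from_f(54.30, 1, 20), 2), 0.73)
  expect_equal(eta_p_sq_from_f(0, 2, 10), 0)
  expect_error(eta_p_sq_from_f(1, 0, 10), "positive")
  cube <- withr::with_seed(12, array(rnorm(5 * 3 * 3), c(5, 3, 3)))
  tab <- rm_anova_two_way(grid_to_df(cube), within = c("A", "B"),
                          subject = "participant", gg = "never")
  expect_equal(tab$eta_p_sq,
               mapply(eta_p_sq_from_f, tab$F, tab$df_effect, tab$df_residual),
               tolerance = 1e-10)
})

test_that("GG correction never increases significance and preserves df ratios", {
  for (s in 1:5) {
    cube <- withr::with_seed(40 + s, array(rnorm(8 * 4 * 3), c(8, 4, 3)))
    cube[, 2, ] <- cube[, 2, ] + 1   # a real effect keeps F above 1
    tab <- rm_anova_two_way(grid_to_df(cube), within = c("A", "B"),
                            subject = "participant", gg = "always")
    # shrinking both dfs never increases significance once F >= 1
    sel <- tab$F >= 1
    expect_true(all(tab$p[sel] >= tab$p_uncorrected[sel] - 1e-12))
    expect_true(all(tab$epsilon_gg <= 1 + 1e-12))
    expect_equal(tab$df_residual_corr / tab$df_effect_corr,
                 tab$df_residual / tab$df_effect, tolerance = 1e-9)
    expect_equal(tab$df_residual[1] / tab$df_effect[1], 8 - 1)
  }
})

test_that("rm-ANOVA type-I error is calibrated under exchangeable nulls", {
  rej <- vapply(1:200, function(s) {
    cube <- withr::with_seed(5000 + s, array(rnorm(12 * 3 * 3), c(12, 3, 3)))
    tab <- rm_anova_two_way(grid_to_df(cube), within = c("A", "B"),
                            subject = "participant")
    tab$p[1] < 0.05
  }, logical(1))
  expect_gte(mean(rej), 0.02)
  expect_lte(mean(rej), 0.10)
})
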