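# deterministic two-sample builder: identical age grids, offsets +/- delta
balanced_two_sample <- function(delta = 0.1, noise_sd = 0, n = 40,
                                seed = 1) {
  set.seed(seed)
  ages <- rep(seq(20, 80, length.out = n), 2)
  samp <- rep(c("s1", "s2"), each = n)
  off <- ifelse(samp == "s1", delta, -delta)
  logT <- 0.45 - 0.002 * ages + off + rnorm(2 * n, 0, noise_sd)
  data.frame(subject_id = sprintf("x%03d", seq_len(2 * n)), sample = samp,
             group = "CTL", sex = "F", age_years = ages,
             hemisphere = "left", roi = "hemisphere",
             avg_thickness_mm = 10^logT, total_area_mm2 = 1e5,
             exposed_area_mm2 = 4e4)
}

test_that("noise-free single-sample data returns the exact slope with b == 0", {
  df <- balanced_two_sample(delta = 0, noise_sd = 0)
  df <- df[df$sample == "s1", ]
  fit <- fit_joint_trend(df, "T")
  expect_true(fit$single_sample)
  expect_equal(unname(fit$slope[[1]]), -0.002, tolerance = 1e-10)
  expect_equal(fit$sigma_residual, 0, tolerance = 1e-10)
  expect_true(all(fit$random_intercepts$b == 0))
  expect_identical(harmonize(df, fit), df)   # b == 0 is the identity
})

test_that("near-noise-free two-sample offsets are recovered as BLUPs", {
  df <- balanced_two_sample(delta = 0.1, noise_sd = 1e-6)
  fit <- fit_joint_trend(df, "T")
  b <- setNames(fit$random_intercepts$b, fit$random_intercepts$sample)
  expect_lt(abs(unname(b["s1"]) - 0.1), 1e-3)
  expect_lt(abs(unname(b["s2"]) + 0.1), 1e-3)
  # predicted random intercepts average to ~0 on a balanced design with
  # moderate noise (at near-zero noise the variance ratio strains the
  # optimizer, so the centering check uses the better-conditioned fit)
  df2 <- balanced_two_sample(delta = 0.1, noise_sd = 0.01)
  fit2 <- fit_joint_trend(df2, "T")
  expect_lt(abs(mean(fit2$random_intercepts$b)),
            1e-3 * sd(fit2$random_intercepts$b))
  h <- harmonize(df, fit)
  m1 <- mean(log10(h$avg_thickness_mm[h$sample == "s1"]))
  m2 <- mean(log10(h$avg_thickness_mm[h$sample == "s2"]))
  expect_lt(abs(m1 - m2), 1e-3)
})

test_that("the generator-default cohort is recovered within tolerance", {
  g <- generate_cohort(recovery_cohort_spec(11))
  fit <- fit_joint_trend(g$records, "T")
  expect_lt(abs(fit$slope[[1]] - (-0.0044)) / fit$slope_se, 3)
  expect_equal(fit$sigma_residual, 0.1, tolerance = 0.15)
  expect_equal(fit$sigma_sample, 0.085, tolerance = 0.15)
  tr <- g$truth$offsets
  tr$b_true <- tr$offset - mean(tr$offset)
  m <- merge(fit$random_intercepts, tr, by = c("sample", "roi"))
  expect_lt(sqrt(mean((m$b - m$b_true)^2)), 0.02)
})

test_that("harmonization removes intercept shifts without moving the slope", {
  df <- balanced_two_sample(delta = 0.1, noise_sd = 0)
  fit <- fit_joint_trend(df, "T")
  h <- harmonize(df, fit)
  refit <- fit_joint_trend(h, "T")
  expect_lt(abs(fit$slope[[1]] - refit$slope[[1]]), 1e-6)
  # idempotence: refitting on harmonized data leaves ~no shift to remove
  expect_lt(max(abs(refit$random_intercepts$b)), 1e-3)
})

test_that("harmonization shrinks cross-sample spread on the default cohort", {
  g <- generate_cohort(recovery_cohort_spec(21))
  fit <- fit_joint_trend(g$records, "T")
  h <- harmonize(g$records, fit)
  adj_means <- function(df) {
    r <- resid(lm(log10(avg_thickness_mm) ~ age_years, data = df))
    tapply(r, df$sample, mean)
  }
  expect_lt(var(adj_means(h)), 0.5 * var(adj_means(g$records)))
})

test_that("K, S, I from harmonized primaries equal the shifted linear combination", {
  g <- generate_cohort(recovery_cohort_spec(31))
  h <- harmonize_cohort(g$records)
  aug_before <- add_folding_coords(g$records)
  aug_after <- add_folding_coords(h$records)
  # each primary was shifted by its own b on the log scale; K after must
  # equal K before minus the same combination of shifts (exact commutation)
  shift <- lapply(h$fits, function(f)
    setNames(f$random_intercepts$b, f$random_intercepts$sample))
  # x_t2 = 2 log10 T shifts by 2 bT, and K takes 1/4 of x_t2
  bK <- shift$A_T[g$records$sample] - (5 / 4) * shift$A_E[g$records$sample] +
    (1 / 2) * shift$T[g$records$sample]
  expect_lt(max(abs(aug_after$K - (aug_before$K - unname(bK)))), 1e-12)
})

test_that("records from an unseen sample error in strict mode and pass leniently", {
  df <- balanced_two_sample()
  fit <- fit_joint_trend(df, "T")
  new <- df[1, ]
  new$sample <- "mystery"
  expect_error(harmonize(new, fit, strict = TRUE), "mystery")
  expect_warning(out <- harmonize(new, fit, strict = FALSE), "mystery")
  expect_equal(out$avg_thickness_mm, new$avg_thickness_mm)
})

test_that("AD rows are shifted with CTL-derived offsets of their sample", {
  df <- balanced_two_sample(delta = 0.1, noise_sd = 1e-6)
  ad <- df[df$sample == "s1", ][1:5, ]
  ad$group <- "AD"
  ad$subject_id <- paste0("ad", 1:5)
  all_rows <- rbind(df, ad)
  fit <- fit_joint_trend(all_rows, "T", groups_for_fit = "CTL")
  expect_equal(fit$n_obs, nrow(df))   # AD rows did not inform the fit
  h <- harmonize(all_rows, fit)
  b1 <- setNames(fit$random_intercepts$b, fit$random_intercepts$sample)["s1"]
  expect_equal(log10(h$avg_thickness_mm[h$group == "AD"]),
               log10(ad$avg_thickness_mm) - unname(b1), tolerance = 1e-12)
})

test_that("de-aging zeroes the age trend at any reference age", {
  df <- balanced_two_sample(delta = 0, noise_sd = 0)
  fit <- fit_joint_trend(df, "T")
  d <- deage(df, fit, 46)
  refit <- fit_joint_trend(d, "T")
  expect_lt(abs(refit$slope[[1]]), 1e-6)
  # reference age equal to a subject's own age leaves that row unchanged
  row <- df[5, ]
  d1 <- deage(row, fit, row$age_years)
  expect_equal(d1$avg_thickness_mm, row$avg_thickness_mm)
  # stochastic cohort: residual age correlation is negligible
  g <- generate_cohort(recovery_cohort_spec(41))
  fitg <- fit_joint_trend(g$records, "T")
  dg <- deage(harmonize(g$records, fitg), fitg, 46)
  expect_lt(abs(cor(dg$age_years, log10(dg$avg_thickness_mm))), 0.05)
})

test_that("a boundary variance estimate is flagged, not hidden", {
  df <- balanced_two_sample(delta = 0, noise_sd = 0.05, seed = 9)
  fit <- fit_joint_trend(df, "T")   # no real sample effect -> sigma_b ~ 0
  expect_true(fit$boundary)
  expect_gte(fit$sigma_sample, 0)
})
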