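# small deterministic two-group table with exact linear K trends
two_group_k <- function(slope_ctl = -8.6e-4, slope_ad = 0, noise = 0,
                        n = 30, seed = 1) {
  set.seed(seed)
  ages <- rep(seq(50, 90, length.out = n), 2)
  grp <- rep(c("CTL", "AD"), each = n)
  K <- ifelse(grp == "CTL", -0.51 + slope_ctl * ages,
              -0.552 + slope_ad * ages) + rnorm(2 * n, 0, noise)
  data.frame(subject_id = sprintf("q%03d", seq_len(2 * n)), sample = "s1",
             group = grp, sex = "M", age_years = ages, hemisphere = "left",
             roi = "hemisphere", K = K)
}

test_that("noise-free linear trends are recovered exactly", {
  df <- two_group_k()
  fits <- fit_trajectories(df, variables = "K")
  k_ctl <- fits[fits$group == "CTL", ]
  expect_equal(k_ctl$slope, -8.6e-4, tolerance = 1e-12)
  expect_equal(fits[fits$group == "AD", "slope"], 0, tolerance = 1e-15)
  expect_true(k_ctl$ci_lo <= k_ctl$slope && k_ctl$slope <= k_ctl$ci_hi)
  # percent per year keeps the slope's sign (K baseline is negative)
  expect_lt(k_ctl$percent_per_year, 0)
})

test_that("simulated CTL/AD K slopes are recovered within their CIs", {
  g <- generate_cohort(contrast_cohort_spec(2))
  aug <- add_folding_coords(g$records)
  fits <- fit_trajectories(aug, variables = "K", rois = "hemisphere")
  ctl <- fits[fits$group == "CTL", ]
  ad <- fits[fits$group == "AD", ]
  expect_true(ctl$ci_lo <= -8.6e-4 && -8.6e-4 <= ctl$ci_hi)
  expect_true(ad$ci_lo <= 0 && 0 <= ad$ci_hi)
  expect_equal(ctl$n, 800)
})

test_that("degenerate cells are skipped with a warning naming the cell", {
  df <- two_group_k()
  df$age_years[df$group == "AD"] <- 70   # single age -> degenerate
  expect_warning(fits <- fit_trajectories(df, variables = "K"), "AD")
  expect_false("AD" %in% fits$group)
  expect_match(attr(fits, "skipped"), "AD")
})

test_that("slope contrasts match the classical two-line interaction t-test", {
  df <- two_group_k(noise = 0.01, n = 12, seed = 4)
  cs <- compare_slopes(df, "K", groups = c("AD", "CTL"), adjust = "none")
  # explicit small-n oracle: pooled-variance interaction t statistic
  g1 <- df[df$group == "AD", ]; g2 <- df[df$group == "CTL", ]
  f1 <- lm(K ~ age_years, g1); f2 <- lm(K ~ age_years, g2)
  sp2 <- (sum(resid(f1)^2) + sum(resid(f2)^2)) / (nrow(g1) + nrow(g2) - 4)
  sxx <- function(g) sum((g$age_years - mean(g$age_years))^2)
  se <- sqrt(sp2 * (1 / sxx(g1) + 1 / sxx(g2)))
  est <- unname(coef(f1)[2] - coef(f2)[2])
  tval <- est / se
  pval <- 2 * pt(-abs(tval), df = nrow(g1) + nrow(g2) - 4)
  expect_equal(cs$estimate, est, tolerance = 1e-10)
  expect_equal(cs$se, se, tolerance = 1e-10)
  expect_equal(cs$p_value, pval, tolerance = 1e-10)
})

test_that("identical groups give a null contrast and noise-free ones the exact difference", {
  df <- two_group_k(slope_ctl = -2e-3, slope_ad = -2e-3, noise = 0.01,
                    seed = 6)
  df$K[df$group == "AD"] <- df$K[df$group == "CTL"]  # clone the data
  cs <- compare_slopes(df, "K", adjust = "none")
  expect_equal(cs$estimate, 0, tolerance = 1e-12)
  expect_gt(cs$p_value, 0.99)

  exact <- two_group_k(slope_ctl = -9.0e-4, slope_ad = 0)
  cs2 <- compare_slopes(exact, "K", adjust = "none")
  expect_equal(cs2$estimate, 9.0e-4, tolerance = 1e-12)  # AD - CTL
})

test_that("unknown adjustment methods are refused", {
  expect_error(compare_slopes(two_group_k(), "K", adjust = "holm"))
})

test_that("slope estimates ignore per-sample constant shifts on balanced designs", {
  df <- two_group_k(noise = 0.01, seed = 8)
  df2 <- rbind(df, transform(df, sample = "s2",
                             subject_id = paste0("r", subject_id)))
  shifted <- df2
  shifted$K <- shifted$K + ifelse(shifted$sample == "s2", 0.25, -0.1)
  f0 <- fit_trajectories(df2, variables = "K")
  f1 <- fit_trajectories(shifted, variables = "K")
  expect_equal(f1$slope, f0$slope, tolerance = 1e-8)
  c0 <- compare_slopes(df2, "K", adjust = "none")
  c1 <- compare_slopes(shifted, "K", adjust = "none")
  expect_equal(c1$estimate, c0$estimate, tolerance = 1e-8)
})

test_that("per-decade alpha bins cover the truth and omit thin bins", {
  g <- generate_cohort(scaling_cohort_spec(9, n = 600))
  abd <- alpha_by_decade(g$records, min_n = 10)
  expect_gt(nrow(abd), 3)
  expect_true(all(abd$ci_lo <= 1.25 & 1.25 <= abd$ci_hi))
  expect_true(all(abd$n >= 10))
  # raising the threshold above any bin's n omits every bin
  abd2 <- alpha_by_decade(g$records, min_n = 10000)
  expect_equal(nrow(abd2), 0)
  expect_gt(nrow(attr(abd2, "omitted")), 0)
  # removing one bin's rows leaves other bins untouched
  drop <- g$records$age_years < 30
  abd3 <- alpha_by_decade(g$records[!drop, ], min_n = 10)
  shared <- merge(as.data.frame(abd), as.data.frame(abd3),
                  by = c("group", "bin_low"))
  expect_equal(shared$alpha.x, shared$alpha.y, tolerance = 1e-12)
  # two groups sharing the same rows produce identical bins
  dup <- g$records
  dup$group <- "AD"
  both <- alpha_by_decade(rbind(g$records, dup), min_n = 10)
  expect_equal(both$alpha[both$group == "AD"],
               both$alpha[both$group == "CTL"])
})

test_that("baseline bands join fits with budgets and cover held-out controls", {
  df <- two_group_k(noise = 0.016, n = 200, seed = 10)
  fits <- fit_trajectories(df, variables = "K")
  budget <- structure(list(variable = "K", sigma_natural = 0.016,
                           sigma_random = 0.0017, sigma_sample = 0.021,
                           sigma_total = total_sigma(0.016, 0.0017, 0.021),
                           boundary = FALSE), class = "uncertainty_budget")
  bl <- baseline_table(fits, list(K = budget))
  band <- baseline_band(bl, "K", "CTL", "hemisphere", ages = c(50, 70))
  row <- bl[bl$group == "CTL", ]
  expect_equal(band$value, row$intercept + row$slope * c(50, 70))
  expect_equal(band$hi - band$value, rep(budget$sigma_total, 2))
  # +/- 1 sigma_natural-dominated band should cover most held-out controls
  hold <- two_group_k(noise = 0.016, n = 400, seed = 11)
  hold <- hold[hold$group == "CTL", ]
  pred <- row$intercept + row$slope * hold$age_years
  cover <- mean(abs(hold$K - pred) <= budget$sigma_total)
  expect_gte(cover, 0.6)
  # budgets for unknown variables are refused; missing ones are flagged
  expect_error(baseline_table(fits, list(S = budget)), "without a trajectory")
  bl2 <- baseline_table(fits, list())
  expect_true(all(bl2$missing_budget))
})
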