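# Shared scenario constructors used by module and acceptance tests.
# Each takes a seed so replicate loops stay reproducible.

# single-sample scaling-law cohort: constant K, exposed areas spanning one
# decade, pure response noise sd 0.02 on log10(A_T sqrt(T))
scaling_cohort_spec <- function(seed, n = 500, noise = 0.02) {
  cohort_spec(
    samples = data.frame(name = "s1", n_subjects = n,
                         age_low = 20, age_high = 80),
    groups = list(CTL = list(
      K = list(intercept = -0.55, slope = 0, sigma = 0),
      S = list(intercept = 9.0, slope = 0, sigma = 0),
      I = list(intercept = 10.4, slope = 0, sigma = 0, spread = 1.5))),
    generation_mode = "ksi_latent", sigma_response = noise, seed = seed)
}

# the 9-sample recovery scenario (generator defaults: shared log10 slope
# -0.0044/yr for T, sigma_natural 0.1, sigma_sample 0.085)
recovery_cohort_spec <- function(seed) cohort_spec(seed = seed)

# two-site CTL/AD cohort for slope-contrast power: CTL K slope -8.6e-4/yr,
# AD flat, K noise 0.016, 800 hemispheres per group
contrast_cohort_spec <- function(seed) {
  gp <- default_group_params("ksi_latent")
  gp$CTL$K$sigma <- 0.016
  gp$AD$K$sigma <- 0.016
  cohort_spec(samples = data.frame(name = c("sA", "sB"), n_subjects = 400,
                                   age_low = c(40, 55), age_high = c(96, 92)),
              groups = gp, generation_mode = "ksi_latent", seed = seed)
}

# multisite regression data for evidence tests: 6 samples x 30 points,
# fixed ten-fold spread of per-sample dispersions (the common-slope /
# per-sample-dispersion structure of the reference trend model); when
# per_sample_slopes, deterministic slope offsets of ~3 estimation SEs
evidence_cohort_data <- function(seed, per_sample_slopes = FALSE, n = 30) {
  sig <- c(0.03, 0.05, 0.08, 0.12, 0.2, 0.3)
  sd_x <- (90 - 20) / sqrt(12)
  samples <- data.frame(name = sprintf("s%d", 1:6), n_subjects = n,
                        age_low = 20, age_high = 90, sigma_natural = sig)
  if (per_sample_slopes)
    samples$slope_offset <- 3 * sig / (sd_x * sqrt(n)) *
      c(-1, 1, -1, 1, -1, 1)
  sp <- cohort_spec(samples = samples, seed = seed)
  g <- generate_cohort(sp)
  morph_to_evidence_data(g$records, "T")
}

expect_all_finite <- function(x) expect_true(all(is.finite(unlist(x))))
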