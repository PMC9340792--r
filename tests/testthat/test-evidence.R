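# closed-form log-evidence for one sample, mu = b, known sigma, uniform
# prior on b over [-W, W]: a Gaussian integral expressible via pnorm
const_model_logz <- function(y, sigma, W) {
  n <- length(y); ybar <- mean(y); ss <- sum((y - ybar)^2)
  -log(2 * W) - n / 2 * log(2 * pi * sigma^2) - ss / (2 * sigma^2) +
    0.5 * log(2 * pi * sigma^2 / n) +
    log(pnorm((W - ybar) * sqrt(n) / sigma) -
          pnorm((-W - ybar) * sqrt(n) / sigma))
}

test_that("quadrature matches the closed-form Gaussian integral to 1e-6", {
  set.seed(7)
  sigma <- 0.5
  y <- rnorm(20, 0.3, sigma)
  W <- abs(mean(y)) + 5 * sigma / sqrt(20)
  ev <- log_marginal_likelihood(
    trend_model("const", sigma_fixed = sigma),
    list(s1 = list(x = 1:20, y = y)),
    priors = list(shared = list(),
                  per_sample = list(s1 = list(b = c(-W, W)))))
  expect_equal(ev$log_z, const_model_logz(y, sigma, W), tolerance = 1e-6)
  expect_identical(ev$backend, "gauss-legendre")
})

test_that("widening an irrelevant prior pays the expected Occam penalty", {
  set.seed(8)
  sigma <- 0.4
  y <- rnorm(30, 0, sigma)
  d <- list(s1 = list(x = 1:30, y = y))
  m <- trend_model("const", sigma_fixed = sigma)
  W <- 6 * sigma / sqrt(30)
  z1 <- log_marginal_likelihood(m, d, priors = list(
    shared = list(), per_sample = list(s1 = list(b = c(-W, W)))))$log_z
  z10 <- log_marginal_likelihood(m, d, priors = list(
    shared = list(), per_sample = list(s1 = list(b = c(-10 * W, 10 * W)))))$log_z
  expect_equal(z10 - z1, -log(10), tolerance = 0.01)
})

test_that("odds and posterior probabilities follow the evidence arithmetic", {
  ev <- function(id, lz) structure(
    list(model_id = id, log_z = lz, error_estimate = 0, edge_mass = 0,
         fingerprint = "same", n_obs = 10), class = "model_evidence")
  tab <- compare_models(list(ev("base", -100), ev("ii", -103)))
  expect_equal(tab$model, c("base", "ii"))
  expect_equal(tab$odds_vs_best[2], exp(-3))
  expect_equal(tab$posterior_prob, c(exp(3), 1) / (exp(3) + 1),
               tolerance = 1e-12)
  expect_equal(sum(tab$posterior_prob), 1)
  # a single evidence gets probability one
  expect_equal(compare_models(list(ev("base", -5)))$posterior_prob, 1)
  # two structurally identical models tie at one half
  tie <- compare_models(list(ev("base", -50), ev("i", -50)))
  expect_equal(tie$posterior_prob, c(0.5, 0.5))
  # mismatched data fingerprints are refused
  bad <- ev("ii", -1); bad$fingerprint <- "other"
  expect_error(compare_models(list(ev("base", -1), bad)), "fingerprint")
})

test_that("evidence is invariant under sample relabeling", {
  d <- evidence_cohort_data(3)
  z1 <- log_marginal_likelihood("base", d, n_nodes = 32,
                                refine = FALSE)$log_z
  perm <- rev(seq_along(d))
  d2 <- d[perm]
  z2 <- log_marginal_likelihood("base", d2, n_nodes = 32,
                                refine = FALSE)$log_z
  expect_equal(z1, z2, tolerance = 1e-9)
})

test_that("the common-slope model wins on data generated under it", {
  wins <- vapply(1:8, function(s) {
    d <- evidence_cohort_data(s)
    evs <- lapply(c("base", "i", "ii", "iii", "iv"), function(m)
      log_marginal_likelihood(m, d, n_nodes = 40, refine = FALSE))
    compare_models(evs)$model[1]
  }, character(1))
  expect_gte(sum(wins == "base"), 7)
})

test_that("per-sample-slope data hands the win to the per-slope model", {
  wins <- vapply(1:8, function(s) {
    d <- evidence_cohort_data(100 + s, per_sample_slopes = TRUE)
    evs <- lapply(c("base", "i", "ii", "iii", "iv"), function(m)
      log_marginal_likelihood(m, d, n_nodes = 40, refine = FALSE))
    compare_models(evs)$model[1]
  }, character(1))
  expect_gte(sum(wins == "ii"), 7)
})

test_that("quadratic data favor the quadratic trend model", {
  gen_quad <- function(seed) {
    set.seed(seed)
    lapply(setNames(nm = sprintf("s%d", 1:4)), function(j) {
      x <- runif(40, 20, 90)
      # curvature: c * (range/2)^2 / 2 = 0.18, >= 3 residual sds of 0.05
      y <- 3e-4 * x^2 - 0.0044 * x + rnorm(1, 0.45, 0.085) +
        rnorm(40, 0, 0.05)
      list(x = x, y = y)
    })
  }
  wins <- vapply(1:5, function(s) {
    d <- gen_quad(s)
    evs <- lapply(c("base", "iv"), function(m)
      log_marginal_likelihood(m, d, n_nodes = 40, refine = FALSE))
    compare_models(evs)$model[1]
  }, character(1))
  expect_gte(sum(wins == "iv"), 4)
})

test_that("the slope posterior concentrates on the generating value", {
  # noise-free line: posterior mode equals the slope to grid tolerance
  x <- seq(20, 80, length.out = 30)
  d <- list(s1 = list(x = x, y = -0.002 * x + 0.5))
  post <- parameter_posterior("base", d, "a")
  expect_equal(post$mode, -0.002, tolerance = 1e-6)

  # conjugate case: known sigma, wide uniform prior; the marginal of b is
  # the analytic Gaussian posterior
  set.seed(10)
  sigma <- 0.3
  y <- rnorm(40, 1.0, sigma)
  W <- 6 * sigma / sqrt(40)
  post_b <- parameter_posterior(
    trend_model("const", sigma_fixed = sigma),
    list(s1 = list(x = 1:40, y = y)), "b", sample_name = "s1",
    priors = list(shared = list(),
                  per_sample = list(s1 = list(b = mean(y) + c(-W, W)))))
  expect_equal(post_b$mode, mean(y), tolerance = 1e-3)
  an_ci <- mean(y) + c(-1, 1) * qnorm(0.975) * sigma / sqrt(40)
  expect_equal(post_b$ci95, an_ci, tolerance = 1e-3)
})

test_that("the Bayesian slope agrees with the REML slope on a cohort", {
  g <- generate_cohort(recovery_cohort_spec(51))
  fit <- fit_joint_trend(g$records, "T")
  d <- morph_to_evidence_data(g$records, "T")
  post <- parameter_posterior("base", d, "a", n_nodes = 32)
  expect_lt(abs(post$mode - fit$slope[[1]]), fit$slope_se)
  expect_true(post$ci95[1] < fit$slope[[1]] && fit$slope[[1]] < post$ci95[2])
})

test_that("posterior mass piling at a prior edge raises a warning", {
  set.seed(11)
  y <- rnorm(25, 5, 0.2)   # data far outside the prior window below
  d <- list(s1 = list(x = 1:25, y = y))
  expect_warning(
    ev <- log_marginal_likelihood(
      trend_model("const", sigma_fixed = 0.2), d,
      priors = list(shared = list(),
                    per_sample = list(s1 = list(b = c(-1, 4.9)))),
      refine = FALSE),
    "prior-range edge")
  expect_gt(ev$edge_mass, 0.01)
  # a comfortably wide prior raises no such warning
  expect_silent(
    log_marginal_likelihood(
      trend_model("const", sigma_fixed = 0.2), d,
      priors = list(shared = list(),
                    per_sample = list(s1 = list(b = c(0, 10)))),
      refine = FALSE))
})
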