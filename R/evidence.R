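#' Bayesian selection among age-trend models by marginal likelihood
#'
#' The harmonization model (one shared slope, per-sample intercepts) is
#' validated against alternatives by comparing marginal likelihoods
#' (evidences).  For data split into J samples, a candidate model M with
#' mean function \eqn{\mu(x; A)} and Gaussian dispersion gives
#' \deqn{P(M|D) = \prod_{j=1}^{J} \int dA_{(j)}\, P(A_{(j)}|I)
#'   \prod_{i=1}^{N_j} \frac{1}{\sigma_{(j)}\sqrt{2\pi}}
#'   e^{-[y_{i(j)} - \mu(x_{i(j)}; A)]^2 / 2\sigma_{(j)}^2},}
#' with shared parameters held outside the product over samples.  The
#' integral is computed by nested Gauss-Legendre quadrature, exploiting the
#' factorization over samples given the shared parameters; the marginal
#' likelihood naturally penalizes unnecessary parameters (Occam factor).
#'
#' Candidate models (x = age, y = log10 variable):
#' \describe{
#'   \item{`base`}{\eqn{\mu = a x + b_{(j)}}, per-sample dispersion
#'     \eqn{\sigma_{(j)}} (the harmonization scheme).}
#'   \item{`i`}{\eqn{\mu = a x + b_{(j)}}, one common dispersion.}
#'   \item{`ii`}{\eqn{\mu = a_{(j)} x + b_{(j)}}, per-sample dispersion.}
#'   \item{`iii`}{\eqn{\mu = a_{(j)} x + b_{(j)}}, common dispersion.}
#'   \item{`iv`}{\eqn{\mu = c x^2 + a x + b_{(j)}}, per-sample dispersion.}
#'   \item{`const`}{\eqn{\mu = b_{(j)}} (no trend; mainly for oracle
#'     checks).}
#' }
#' Priors are uniform for location parameters over data-driven ranges (OLS
#' estimate +/- 10 standard errors) and log-uniform for dispersions over
#' \eqn{[\hat\sigma/10, 10\hat\sigma]}; ranges are recorded in the output
#' and can be overridden or scaled for sensitivity analysis.
#'
#' Internally each sample's ages are centered at the sample mean, so the
#' per-sample intercept parameter is the fitted value at the sample's mean
#' age; this decouples intercepts from slopes and keeps the quadrature
#' well-conditioned.  Reported slopes are unaffected.
#'
#' @name evidence
NULL

TREND_MODELS <- c("base", "i", "ii", "iii", "iv", "const")

#' Declare a trend model
#'
#' @param id one of `"base"`, `"i"`, `"ii"`, `"iii"`, `"iv"`, `"const"`.
#' @param sigma_fixed optional known dispersion; when given, no dispersion
#'   parameter is integrated (used for conjugate cross-checks).
#' @return a `trend_model` descriptor.
#' @export
trend_model <- function(id = TREND_MODELS, sigma_fixed = NULL) {
  id <- match.arg(id)
  per_sigma <- id %in% c("base", "ii", "iv", "const")
  structure(list(
    id = id,
    shared = c(if (id %in% c("base", "i", "iv")) "a",
               if (id == "iv") "c",
               if (id %in% c("i", "iii") && is.null(sigma_fixed)) "sigma"),
    per_sample = c("b",
                   if (id %in% c("ii", "iii")) "a_j",
                   if (per_sigma && is.null(sigma_fixed)) "sigma_j"),
    sigma_fixed = sigma_fixed), class = "trend_model")
}

#' Split a morphometric table into per-sample (x, y) regression data
#'
#' @param records morphometric data.frame.
#' @param variable variable name (see [fit_joint_trend()]); primary
#'   variables are logged.
#' @param roi restrict to one ROI (default `"hemisphere"` when present).
#' @return named list (one element per sample) of `list(x = ages, y =
#'   responses)`, the shape [log_marginal_likelihood()] consumes.
#' @export
morph_to_evidence_data <- function(records, variable, roi = NULL) {
  if (is.null(roi) && "roi" %in% names(records)) {
    roi <- if ("hemisphere" %in% records$roi) "hemisphere"
           else records$roi[1]
  }
  if (!is.null(roi)) records <- records[records$roi == roi, , drop = FALSE]
  y <- extract_response(records, variable)
  split_idx <- split(seq_len(nrow(records)), records$sample)
  lapply(split_idx, function(ix) list(x = records$age_years[ix], y = y[ix]))
}

# centered per-sample sufficient statistics for polynomial (<= 2) Gaussian
# regression; everything downstream is O(1) in the sample size
sample_stats <- function(x, y) {
  n <- length(x)
  if (n < 2) stop("every sample needs >= 2 points")
  xbar <- mean(x); u <- x - xbar
  list(n = n, xbar = xbar, ybar = mean(y),
       Sy = sum(y), Syy = sum(y^2),
       Su2 = sum(u^2), Suy = sum(u * y),
       Su3 = sum(u^3), Su4 = sum(u^4), Su2y = sum(u^2 * y))
}

data_fingerprint <- function(data) {
  paste(length(data),
        sum(vapply(data, function(d) length(d$x), numeric(1))),
        format(sum(vapply(data, function(d) sum(d$x) + 2 * sum(d$y) +
                            sum(d$x * d$y), numeric(1))), digits = 12),
        sep = "|")
}

# residual sum of squares over a grid of intercepts b, given slope a and
# quadratic coefficient c (ages centered within sample, so Su = 0)
ssr_over_b <- function(st, a, c, b) {
  A <- st$Syy + c^2 * st$Su4 + a^2 * st$Su2 - 2 * c * st$Su2y -
    2 * a * st$Suy + 2 * a * c * st$Su3
  B <- st$Sy - c * st$Su2
  A + st$n * b^2 - 2 * b * B
}

# per-sample OLS anchors used to center the data-driven prior ranges
sample_anchors <- function(st, sigma_floor) {
  a_hat <- st$Suy / st$Su2
  ssr <- max(ssr_over_b(st, a_hat, 0, st$ybar), 0)
  df <- max(st$n - 2, 1)
  sig <- max(sqrt(ssr / df), sigma_floor)
  list(a_hat = a_hat, b_hat = st$ybar, sigma_hat = sig,
       se_a = sig / sqrt(st$Su2), se_b = sig / sqrt(st$n))
}

default_priors <- function(model, data, se_mult = 10, expand = 1) {
  sigma_floor <- max(1e-8, 1e-6 * stats::sd(unlist(lapply(data, `[[`, "y"))))
  sts <- lapply(data, function(d) sample_stats(d$x, d$y))
  anc <- lapply(sts, sample_anchors, sigma_floor = sigma_floor)
  half <- function(se) expand * se_mult * max(se, sigma_floor)

  # pooled within-sample slope and dispersion for shared parameters
  Su2_tot <- sum(vapply(sts, `[[`, numeric(1), "Su2"))
  a_pool <- sum(vapply(sts, `[[`, numeric(1), "Suy")) / Su2_tot
  ssr_pool <- sum(mapply(function(st) ssr_over_b(st, a_pool, 0, st$ybar),
                         sts))
  n_tot <- sum(vapply(sts, `[[`, numeric(1), "n"))
  sig_pool <- max(sqrt(ssr_pool / max(n_tot - 2 * length(sts), 1)),
                  sigma_floor)
  se_a_pool <- sig_pool / sqrt(Su2_tot)

  shared <- list()
  if ("a" %in% model$shared)
    shared$a <- c(a_pool - half(se_a_pool), a_pool + half(se_a_pool))
  if ("c" %in% model$shared) {
    # pooled quadratic fit with per-sample intercepts for the c anchor
    xs <- unlist(lapply(seq_along(data), function(j)
      data[[j]]$x - sts[[j]]$xbar))
    ys <- unlist(lapply(data, `[[`, "y"))
    sm <- factor(rep(names(data), vapply(data, function(d) length(d$x),
                                         numeric(1))))
    qf <- lm(ys ~ xs + I(xs^2) + sm)
    cs <- summary(qf)$coefficients
    c_hat <- cs["I(xs^2)", 1]
    se_c <- max(cs["I(xs^2)", 2], sigma_floor)
    shared$c <- c(c_hat - half(se_c), c_hat + half(se_c))
  }
  if ("sigma" %in% model$shared)
    shared$sigma <- c(sig_pool / (10 * expand), sig_pool * 10 * expand)

  per_sample <- lapply(names(data), function(j) {
    a <- anc[[j]]
    p <- list(b = c(a$b_hat - half(a$se_b), a$b_hat + half(a$se_b)))
    if ("a_j" %in% model$per_sample)
      p$a_j <- c(a$a_hat - half(a$se_a), a$a_hat + half(a$se_a))
    if ("sigma_j" %in% model$per_sample)
      p$sigma_j <- c(a$sigma_hat / (10 * expand), a$sigma_hat * 10 * expand)
    p
  })
  names(per_sample) <- names(data)
  list(shared = shared, per_sample = per_sample)
}

# location-parameter grid: Gauss-Legendre nodes restricted to the window
# where the likelihood has support, prior density taken over the full range
loc_grid <- function(range, n, center = NULL, halfwidth = NULL) {
  lo <- range[1]; hi <- range[2]
  if (!is.null(center) && !is.null(halfwidth)) {
    lo <- max(lo, center - halfwidth)
    hi <- min(hi, center + halfwidth)
    if (!(hi > lo)) { lo <- range[1]; hi <- range[2] }
  }
  g <- gl_nodes(n, lo, hi)
  list(x = g$x, w = g$w, logprior = -log(range[2] - range[1]))
}

# dispersion grid in t = log(sigma); log-uniform prior => uniform in t
sigma_grid <- function(range, n) {
  g <- gl_nodes(n, log(range[1]), log(range[2]))
  list(t = g$x, w = g$w, logprior = -log(log(range[2] / range[1])))
}

# log of the (b [, sigma]) inner integral for one sample
inner_bsigma <- function(st, a, c, bg, sg) {
  ssr <- ssr_over_b(st, a, c, bg$x)
  ll <- outer(ssr, -0.5 * exp(-2 * sg$t)) -
    rep(st$n * sg$t + 0.5 * st$n * log(2 * pi), each = length(bg$x))
  logsumexp(ll + bg$logprior + sg$logprior, outer(bg$w, sg$w))
}

inner_b_fixed_sigma <- function(st, a, c, bg, sigma) {
  ssr <- ssr_over_b(st, a, c, bg$x)
  ll <- -st$n * log(sigma) - 0.5 * st$n * log(2 * pi) - ssr / (2 * sigma^2)
  logsumexp(ll + bg$logprior, bg$w)
}

# (a_j, b, sigma_j) integral; the centered design makes a_j and b separable
inner_absigma <- function(st, ag, bg, sg) {
  f_a <- st$Su2 * ag$x^2 - 2 * st$Suy * ag$x
  g_b <- st$n * bg$x^2 - 2 * st$Sy * bg$x
  vapply(seq_along(sg$t), function(k) {
    inv2s2 <- 0.5 * exp(-2 * sg$t[k])
    la <- logsumexp(-f_a * inv2s2, ag$w)
    lb <- logsumexp(-g_b * inv2s2, bg$w)
    -st$n * sg$t[k] - 0.5 * st$n * log(2 * pi) - st$Syy * inv2s2 + la + lb
  }, numeric(1)) -> per_sig
  logsumexp(per_sig + ag$logprior + bg$logprior + sg$logprior, sg$w)
}

inner_ab_fixed_sigma <- function(st, ag, bg, sigma) {
  inv2s2 <- 0.5 / sigma^2
  f_a <- st$Su2 * ag$x^2 - 2 * st$Suy * ag$x
  g_b <- st$n * bg$x^2 - 2 * st$Sy * bg$x
  -st$n * log(sigma) - 0.5 * st$n * log(2 * pi) - st$Syy * inv2s2 +
    logsumexp(-f_a * inv2s2, ag$w) + ag$logprior +
    logsumexp(-g_b * inv2s2, bg$w) + bg$logprior
}

# build per-sample grids for a model; windows keep quadrature nodes where
# the likelihood lives (coupling of b with the shared quadratic term c is
# absorbed into the window half-width)
build_grids <- function(model, priors, sts, n_loc, n_sig) {
  lapply(names(sts), function(j) {
    st <- sts[[j]]
    pp <- priors$per_sample[[j]]
    sig_hi <- if (!is.null(pp$sigma_j)) pp$sigma_j[2]
              else model$sigma_fixed %||% exp(mean(log(priors$shared$sigma %||%
                                                         c(1, 1))))
    se_b <- 3 * sig_hi / sqrt(st$n)   # generous: covers sigma above sigma_hat
    c_span <- if (!is.null(priors$shared$c))
      max(abs(priors$shared$c)) * st$Su2 / st$n else 0
    g <- list(b = loc_grid(pp$b, n_loc, st$ybar, 8 * se_b + c_span))
    if (!is.null(pp$a_j))
      g$a_j <- loc_grid(pp$a_j, n_loc, st$Suy / st$Su2,
                        8 * 3 * sig_hi / sqrt(st$Su2))
    if (!is.null(pp$sigma_j)) g$sigma_j <- sigma_grid(pp$sigma_j, n_sig)
    g
  }) -> out
  names(out) <- names(sts)
  out
}

# core evidence pass; returns logZ plus the per-(shared-node) integrand so
# posteriors and diagnostics can reuse it
evidence_pass <- function(model, data, priors, n_loc, n_sig, n_outer) {
  sts <- lapply(data, function(d) sample_stats(d$x, d$y))
  grids <- build_grids(model, priors, sts, n_loc, n_sig)
  J <- length(sts)

  shared_grids <- list()
  for (p in model$shared) {
    shared_grids[[p]] <- if (p == "sigma")
      sigma_grid(priors$shared$sigma, n_outer)
    else loc_grid(priors$shared[[p]], n_outer)
  }
  n_shared <- length(shared_grids)
  if (n_shared == 0) {
    per_j <- vapply(names(sts), function(j) {
      st <- sts[[j]]; g <- grids[[j]]
      if (!is.null(model$sigma_fixed)) {
        if (model$id %in% c("ii", "iii"))
          inner_ab_fixed_sigma(st, g$a_j, g$b, model$sigma_fixed)
        else inner_b_fixed_sigma(st, 0, 0, g$b, model$sigma_fixed)
      } else if (model$id %in% c("ii", "iii")) {
        inner_absigma(st, g$a_j, g$b, g$sigma_j)
      } else {
        inner_bsigma(st, 0, 0, g$b, g$sigma_j)
      }
    }, numeric(1))
    return(list(log_z = sum(per_j), shared_grids = shared_grids,
                node_values = NULL, node_weights = NULL,
                inner_matrix = matrix(per_j, nrow = 1), grids = grids,
                sts = sts))
  }

  node_idx <- expand.grid(lapply(shared_grids, function(g)
    seq_along(g$x %||% g$t)))
  n_nodes_total <- nrow(node_idx)
  inner_matrix <- matrix(NA_real_, n_nodes_total, J)
  logw <- numeric(n_nodes_total)
  for (r in seq_len(n_nodes_total)) {
    sh <- list(a = 0, c = 0, sigma = model$sigma_fixed)
    lw <- 0
    for (p in names(shared_grids)) {
      g <- shared_grids[[p]]
      k <- node_idx[r, p]
      if (p == "sigma") { sh$sigma <- exp(g$t[k]) } else sh[[p]] <- g$x[k]
      lw <- lw + log(g$w[k]) + g$logprior
    }
    logw[r] <- lw
    for (j in seq_len(J)) {
      st <- sts[[j]]; g <- grids[[j]]
      inner_matrix[r, j] <-
        if (model$id %in% c("ii", "iii")) {
          if (is.null(sh$sigma)) inner_absigma(st, g$a_j, g$b, g$sigma_j)
          else inner_ab_fixed_sigma(st, g$a_j, g$b, sh$sigma)
        } else if (is.null(sh$sigma)) {
          inner_bsigma(st, sh$a, sh$c, g$b, g$sigma_j)
        } else {
          inner_b_fixed_sigma(st, sh$a, sh$c, g$b, sh$sigma)
        }
    }
  }
  node_values <- rowSums(inner_matrix)
  log_z <- logsumexp(node_values + logw)
  list(log_z = log_z, shared_grids = shared_grids,
       node_values = node_values, node_weights = logw, node_idx = node_idx,
       inner_matrix = inner_matrix, grids = grids, sts = sts)
}

# per-sample location dimensions: posterior mass at the outermost grid
# node, evaluated at the best shared-parameter node and the anchor
# dispersion of each sample (a cheap but effective prior-coverage check)
inner_edge_mass <- function(model, pass, priors) {
  best <- if (is.null(pass$node_values)) NULL
          else which.max(pass$node_values + pass$node_weights)
  sh <- list(a = 0, c = 0, sigma = model$sigma_fixed)
  if (!is.null(best)) {
    for (p in names(pass$shared_grids)) {
      g <- pass$shared_grids[[p]]
      k <- pass$node_idx[best, p]
      if (p == "sigma") sh$sigma <- exp(g$t[k]) else sh[[p]] <- g$x[k]
    }
  }
  worst <- 0
  for (j in names(pass$sts)) {
    st <- pass$sts[[j]]; g <- pass$grids[[j]]
    sig <- sh$sigma %||% exp(mean(log(priors$per_sample[[j]]$sigma_j)))
    dims <- list(b = g$b)
    if (!is.null(g$a_j)) dims$a_j <- g$a_j
    for (nm in names(dims)) {
      gr <- dims[[nm]]
      ssr <- if (nm == "b") ssr_over_b(st, sh$a %||% 0, sh$c %||% 0, gr$x)
             else st$Su2 * gr$x^2 - 2 * st$Suy * gr$x
      ll <- -ssr / (2 * sig^2)
      post <- gr$w * exp(ll - max(ll))
      post <- post / sum(post)
      worst <- max(worst, post[1], post[length(post)])
    }
  }
  worst
}

# posterior mass in the outermost nodes of each shared dimension
shared_edge_mass <- function(pass) {
  if (is.null(pass$node_values)) return(0)
  post <- exp(pass$node_values + pass$node_weights - pass$log_z)
  worst <- 0
  for (p in names(pass$shared_grids)) {
    nk <- length(pass$shared_grids[[p]]$x %||% pass$shared_grids[[p]]$t)
    k <- pass$node_idx[[p]]
    worst <- max(worst, sum(post[k == 1]), sum(post[k == nk]))
  }
  worst
}

#' Log marginal likelihood of a trend model
#'
#' @param model a [trend_model()] (or a model id string).
#' @param data named list of per-sample `list(x, y)` (see
#'   [morph_to_evidence_data()]); every sample needs >= 2 points.
#' @param priors optional prior specification as returned by the internal
#'   data-driven rule: `list(shared = list(a = c(lo, hi), ...), per_sample =
#'   list(<sample> = list(b = c(lo, hi), ...)))`.  Defaults to OLS estimate
#'   +/- 10 SE for locations, `[sigma_hat/10, 10 sigma_hat]` log-uniform
#'   for dispersions.
#' @param n_nodes Gauss-Legendre nodes per per-sample/1-D shared dimension.
#' @param n_outer nodes per shared dimension when two shared dimensions are
#'   present (model `iv`).
#' @param expand multiply prior half-widths by this factor (sensitivity
#'   analysis).
#' @param refine recompute at half the node counts and report the
#'   difference as `error_estimate`.
#' @return a `model_evidence`: list with `model_id`, `log_z`,
#'   `error_estimate`, `edge_mass` (posterior mass at the prior-range edge;
#'   a warning is issued above 1%), `priors`, `backend`, `fingerprint`,
#'   `n_obs`.
#' @export
log_marginal_likelihood <- function(model, data, priors = NULL,
                                    n_nodes = 48, n_outer = NULL,
                                    expand = 1, refine = TRUE) {
  if (is.character(model)) model <- trend_model(model)
  stopifnot(inherits(model, "trend_model"))
  if (is.null(names(data)) || any(names(data) == ""))
    names(data) <- sprintf("sample%02d", seq_along(data))
  if (is.null(priors)) priors <- default_priors(model, data, expand = expand)
  if (is.null(n_outer))
    n_outer <- if (length(model$shared) >= 2) max(24, n_nodes %/% 2 + 8)
               else n_nodes
  n_sig <- max(24, round(n_nodes * 5 / 6))
  pass <- evidence_pass(model, data, priors, n_nodes, n_sig, n_outer)
  err <- NA_real_
  if (refine) {
    coarse <- evidence_pass(model, data, priors,
                            max(16, round(n_nodes * 2 / 3)),
                            max(16, round(n_sig * 2 / 3)),
                            max(16, round(n_outer * 2 / 3)))
    err <- abs(pass$log_z - coarse$log_z)
  }
  edge <- max(shared_edge_mass(pass), inner_edge_mass(model, pass, priors))
  if (is.finite(edge) && edge > 0.01)
    warning(sprintf(
      "model %s: %.1f%% posterior mass at a prior-range edge; widen priors",
      model$id, 100 * edge))
  structure(list(model_id = model$id, log_z = pass$log_z,
                 error_estimate = err, edge_mass = edge,
                 priors = priors, backend = "gauss-legendre",
                 n_nodes = n_nodes,
                 fingerprint = data_fingerprint(data),
                 n_obs = sum(vapply(data, function(d) length(d$x),
                                    numeric(1)))),
            class = "model_evidence")
}

#' @export
print.model_evidence <- function(x, ...) {
  cat(sprintf("Evidence for model %-5s logZ = %.4f (err est %.2g)\n",
              x$model_id, x$log_z, x$error_estimate))
  invisible(x)
}

#' Rank trend models by posterior probability
#'
#' Posterior model probabilities assume equal prior model probabilities:
#' `p(M_i) = Z_i / sum(Z)`, equivalently `p(M_1) = 1 / (1 + sum O_i1)` with
#' odds `O_ij = Z_i / Z_j`.
#'
#' @param evidences list of `model_evidence` objects computed on the same
#'   data (fingerprints must agree).
#' @return data.frame sorted by decreasing evidence with columns `model`,
#'   `log_z`, `error_estimate`, `odds_vs_best`, `posterior_prob`.
#' @export
compare_models <- function(evidences) {
  stopifnot(length(evidences) >= 1,
            all(vapply(evidences, inherits, logical(1), "model_evidence")))
  fps <- vapply(evidences, `[[`, character(1), "fingerprint")
  if (length(unique(fps)) != 1)
    stop("evidences were computed on different data (fingerprint mismatch)")
  lz <- vapply(evidences, `[[`, numeric(1), "log_z")
  post <- exp(lz - logsumexp(lz))
  ord <- order(lz, decreasing = TRUE)
  data.frame(model = vapply(evidences, `[[`, character(1), "model_id")[ord],
             log_z = lz[ord],
             error_estimate = vapply(evidences, `[[`, numeric(1),
                                     "error_estimate")[ord],
             odds_vs_best = exp(lz[ord] - max(lz)),
             posterior_prob = post[ord],
             row.names = NULL)
}

#' Leave-one-out marginal posterior of a single parameter
#'
#' Marginalizes every free parameter except the target, yielding its
#' posterior density on a grid, the mode and a central 95% credible
#' interval.
#'
#' @inheritParams log_marginal_likelihood
#' @param target `"a"`, `"c"` or `"sigma"` for shared parameters, or
#'   `"b"`/`"a_j"`/`"sigma_j"` combined with `sample_name` for per-sample
#'   parameters.
#' @param sample_name sample label for per-sample targets.
#' @param n_grid grid resolution for the target parameter.
#' @return list with `target`, `mode`, `ci95` (length 2), `grid`
#'   (data.frame `value`, `density`).
#' @export
parameter_posterior <- function(model, data, target, sample_name = NULL,
                                priors = NULL, n_nodes = 48, n_grid = 161) {
  if (is.character(model)) model <- trend_model(model)
  if (is.null(names(data)) || any(names(data) == ""))
    names(data) <- sprintf("sample%02d", seq_along(data))
  if (is.null(priors)) priors <- default_priors(model, data)
  sts <- lapply(data, function(d) sample_stats(d$x, d$y))
  n_sig <- max(24, round(n_nodes * 5 / 6))
  grids <- build_grids(model, priors, sts, n_nodes, n_sig)

  shared_target <- target %in% c("a", "c", "sigma")
  if (shared_target && !(target %in% model$shared))
    stop("'", target, "' is not a shared free parameter of model ",
         model$id)
  if (!shared_target) {
    if (!(target %in% c("b", "a_j", "sigma_j")))
      stop("unknown target '", target, "'")
    if (is.null(sample_name) || !sample_name %in% names(data))
      stop("per-sample target needs a valid sample_name")
    if (!(target %in% model$per_sample))
      stop("'", target, "' is not a free parameter of model ", model$id)
  }

  # target grid: uniform over the (windowed) support used by the quadrature
  tg_range <- if (shared_target) priors$shared[[target]]
              else priors$per_sample[[sample_name]][[target]]
  if (target %in% c("sigma", "sigma_j")) {
    tvals <- exp(seq(log(tg_range[1]), log(tg_range[2]),
                     length.out = n_grid))
  } else {
    win <- if (shared_target) loc_grid(tg_range, 3)
           else grids[[sample_name]][[target]]
    lo <- min(win$x); hi <- max(win$x)
    tvals <- seq(lo, hi, length.out = n_grid)
  }

  log_dens <- vapply(tvals, function(tv) {
    mod2 <- model
    pri2 <- priors
    if (shared_target) {
      # condition on the target by removing it from the shared set
      mod2$shared <- setdiff(model$shared, target)
      if (target == "sigma") mod2$sigma_fixed <- tv
      fix_a <- if (target == "a") tv else NULL
      fix_c <- if (target == "c") tv else NULL
      pass <- evidence_pass_fixed(mod2, data, pri2, n_nodes, n_sig,
                                  fix_a = fix_a, fix_c = fix_c, grids = grids,
                                  sts = sts)
    } else {
      pass <- evidence_pass_fixed(model, data, pri2, n_nodes, n_sig,
                                  fix_sample = sample_name,
                                  fix_param = target, fix_value = tv,
                                  grids = grids, sts = sts)
    }
    pass
  }, numeric(1))

  # conditioning on a dispersion must carry its (non-uniform) log-uniform
  # prior density 1/(sigma * L); location priors are flat and drop out
  if (target %in% c("sigma", "sigma_j")) log_dens <- log_dens - log(tvals)

  m <- max(log_dens)
  dens <- exp(log_dens - m)
  dx <- diff(tvals)
  cell <- c(dx[1] / 2, (dx[-1] + dx[-length(dx)]) / 2,
            dx[length(dx)] / 2)
  z <- sum(dens * cell)
  dens <- dens / z
  # midpoint rule: each node's mass sits at its center, so the CDF at the
  # node is the cumulative mass minus half the node's own cell
  cdf <- cumsum(dens * cell) - dens * cell / 2
  qfun <- function(p) stats::approx(cdf, tvals, xout = p, rule = 2)$y
  list(target = if (shared_target) target
                else paste0(target, "[", sample_name, "]"),
       mode = tvals[which.max(dens)],
       ci95 = c(qfun(0.025), qfun(0.975)),
       grid = data.frame(value = tvals, density = dens))
}

# evidence with one parameter held fixed (target conditioning); shares the
# grids/stats computed by the caller
evidence_pass_fixed <- function(model, data, priors, n_loc, n_sig,
                                fix_a = NULL, fix_c = NULL,
                                fix_sample = NULL, fix_param = NULL,
                                fix_value = NULL, grids, sts) {
  J <- length(sts)
  shared_grids <- list()
  for (p in model$shared) {
    if (p == "a" && !is.null(fix_a)) next
    if (p == "c" && !is.null(fix_c)) next
    shared_grids[[p]] <- if (p == "sigma")
      sigma_grid(priors$shared$sigma, n_loc)
    else loc_grid(priors$shared[[p]], n_loc)
  }

  inner_one <- function(j, sh) {
    st <- sts[[j]]; g <- grids[[j]]
    fixed_here <- identical(names(sts)[j], fix_sample)
    if (model$id %in% c("ii", "iii")) {
      ag <- g$a_j; bg <- g$b
      if (fixed_here && fix_param == "a_j")
        ag <- list(x = fix_value, w = 1, logprior = ag$logprior)
      if (fixed_here && fix_param == "b")
        bg <- list(x = fix_value, w = 1, logprior = bg$logprior)
      if (fixed_here && fix_param == "sigma_j")
        return(inner_ab_fixed_sigma(st, ag, bg, fix_value) +
                 g$sigma_j$logprior)
      if (is.null(sh$sigma)) inner_absigma(st, ag, bg, g$sigma_j)
      else inner_ab_fixed_sigma(st, ag, bg, sh$sigma)
    } else {
      bg <- g$b
      if (fixed_here && fix_param == "b")
        bg <- list(x = fix_value, w = 1, logprior = bg$logprior)
      if (fixed_here && fix_param == "sigma_j")
        return(inner_b_fixed_sigma(st, sh$a, sh$c, bg, fix_value) +
                 g$sigma_j$logprior)
      if (is.null(sh$sigma)) inner_bsigma(st, sh$a, sh$c, bg, g$sigma_j)
      else inner_b_fixed_sigma(st, sh$a, sh$c, bg, sh$sigma)
    }
  }

  base_shared <- list(a = fix_a %||% 0, c = fix_c %||% 0,
                      sigma = model$sigma_fixed)
  if (length(shared_grids) == 0) {
    return(sum(vapply(seq_len(J), inner_one, numeric(1), sh = base_shared)))
  }
  node_idx <- expand.grid(lapply(shared_grids, function(g)
    seq_along(g$x %||% g$t)))
  vals <- numeric(nrow(node_idx))
  for (r in seq_len(nrow(node_idx))) {
    sh <- base_shared
    lw <- 0
    for (p in names(shared_grids)) {
      g <- shared_grids[[p]]
      k <- node_idx[r, p]
      if (p == "sigma") sh$sigma <- exp(g$t[k]) else sh[[p]] <- g$x[k]
      lw <- lw + log(g$w[k]) + g$logprior
    }
    vals[r] <- sum(vapply(seq_len(J), inner_one, numeric(1), sh = sh)) + lw
  }
  logsumexp(vals)
}
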