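#' Uncertainty budgets for morphometric variables
#'
#' Three uncorrelated error tiers are combined in quadrature:
#' \deqn{\sigma_X^2 = \sigma_{Natural}^2 + \sigma_{Random}^2 +
#'   \sigma_{Sample}^2}
#' where \eqn{\sigma_{Natural}} is the residual standard deviation of the
#' harmonization mixed model (inter-individual biological spread),
#' \eqn{\sigma_{Random}} the repeated-measure (acquisition + processing)
#' noise estimated from test-retest sets, and \eqn{\sigma_{Sample}} the
#' random-intercept standard deviation (between-sample systematic shift).
#'
#' @name uncertainty_budget
NULL

#' Repeated-measure noise: mean within-subject standard deviation
#'
#' Per subject, the sample standard deviation (n-1 denominator) of the
#' repeats; then the unweighted mean across subjects.  No bias correction is
#' applied, so with r repeats the estimator's expectation is
#' c4(r) * sigma (c4(3) = sqrt(pi)/2 = 0.8862): a known, documented downward
#' bias of the mean-SD estimator.
#'
#' @param repeats data.frame from [generate_repeats()] (columns
#'   `subject_id`, `repeat_idx`, `avg_thickness_mm`, `total_area_mm2`,
#'   `exposed_area_mm2`), or any data.frame with `subject_id` plus the
#'   column named by `variable`.
#' @param variable `"T"`, `"A_T"`, `"A_E"`, `"GI"`, `"K"`, `"S"`, `"I"` or a
#'   raw column name.  For K/S/I each repeat is first mapped through the
#'   basis change ([compute_ksi()]); primary variables and GI are taken on
#'   the log10 scale by default so they are commensurate with the
#'   harmonization model's residual scale.
#' @param scale `"log10"` (default, for positive measurement-scale
#'   variables) or `"natural"`.
#' @param s_variant basis variant for the K/S/I propagation route.
#' @return the mean within-subject sd (a scalar), with attribute
#'   `per_subject` (data.frame subject_id/sd/n).
#' @export
repeated_measures_sd <- function(repeats, variable, scale = c("log10",
                                                              "natural"),
                                 s_variant = c("orthogonal", "printed")) {
  scale <- match.arg(scale)
  s_variant <- match.arg(s_variant)
  stopifnot_cols(repeats, "subject_id", "repeats")
  if (variable %in% c("K", "S", "I")) {
    lc <- to_log_coords(repeats$avg_thickness_mm, repeats$total_area_mm2,
                        repeats$exposed_area_mm2)
    vals <- compute_ksi(lc, s_variant)[[variable]]
  } else if (variable == "GI") {
    vals <- compute_gi(repeats$total_area_mm2, repeats$exposed_area_mm2)
    if (scale == "log10") vals <- log10(vals)
  } else {
    col <- variable_column(variable)
    stopifnot_cols(repeats, col, "repeats")
    vals <- repeats[[col]]
    if (scale == "log10" && variable_is_logged(variable)) {
      if (any(vals <= 0)) stop("cannot log non-positive values")
      vals <- log10(vals)
    }
  }
  sizes <- table(repeats$subject_id)
  ok_ids <- names(sizes)[sizes >= 2]
  dropped <- setdiff(names(sizes), ok_ids)
  if (length(dropped))
    warning(length(dropped), " subject(s) with < 2 repeats excluded")
  if (!length(ok_ids))
    stop("no subject has >= 2 repeated measurements")
  keep <- repeats$subject_id %in% ok_ids
  per <- tapply(vals[keep], repeats$subject_id[keep], sd)
  out <- mean(per)
  attr(out, "per_subject") <- data.frame(subject_id = names(per),
                                         sd = as.numeric(per),
                                         n = as.integer(sizes[names(per)]))
  out
}

#' Combine uncertainty components in quadrature
#'
#' @param sigma_natural,sigma_random,sigma_sample non-negative components
#'   (same units).
#' @return `sqrt(sigma_natural^2 + sigma_random^2 + sigma_sample^2)`.
#' @export
total_sigma <- function(sigma_natural, sigma_random, sigma_sample) {
  comp <- c(sigma_natural, sigma_random, sigma_sample)
  if (any(!is.finite(comp)) || any(comp < 0))
    stop("uncertainty components must be finite and >= 0")
  sqrt(sigma_natural^2 + sigma_random^2 + sigma_sample^2)
}

#' Assemble the uncertainty budget for one variable
#'
#' @param fit a [fit_joint_trend()] result; supplies
#'   `sigma_natural` (residual sd) and `sigma_sample` (random-intercept sd).
#' @param sigma_random repeated-measure sd (from [repeated_measures_sd()]).
#' @param reference_intercept optional reference value (e.g. the healthy-
#'   control fixed intercept) used to express the total as a percentage.
#' @return an `uncertainty_budget`: list with `variable`, the three
#'   components, `sigma_total`, optional `percent_of_intercept`, and
#'   `boundary` carried over from the fit.
#' @export
build_budget <- function(fit, sigma_random, reference_intercept = NULL) {
  stopifnot(inherits(fit, "harmonization_fit"))
  b <- list(variable = fit$variable,
            sigma_natural = fit$sigma_residual,
            sigma_random = as.numeric(sigma_random),
            sigma_sample = fit$sigma_sample,
            boundary = isTRUE(fit$boundary))
  b$sigma_total <- total_sigma(b$sigma_natural, b$sigma_random,
                               b$sigma_sample)
  if (!is.null(reference_intercept) && is.finite(reference_intercept) &&
      reference_intercept != 0)
    b$percent_of_intercept <- 100 * b$sigma_total / abs(reference_intercept)
  structure(b, class = "uncertainty_budget")
}

#' @export
print.uncertainty_budget <- function(x, ...) {
  cat(sprintf("Uncertainty budget for %s\n", x$variable))
  cat(sprintf("  sigma_natural = %.4g, sigma_random = %.4g, sigma_sample = %.4g\n",
              x$sigma_natural, x$sigma_random, x$sigma_sample))
  cat(sprintf("  sigma_total = %.4g", x$sigma_total))
  if (!is.null(x$percent_of_intercept))
    cat(sprintf(" (%.2f%% of reference intercept)", x$percent_of_intercept))
  cat("\n")
  if (x$boundary) cat("  note: sigma_sample estimated at boundary\n")
  invisible(x)
}
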