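#' Multisite harmonization by mixed-model sample shifts
#'
#' Heterogeneous acquisition and processing shift each site's morphometrics
#' by an approximately constant factor, i.e. an additive offset on the log10
#' scale.  The harmonization model is a linear mixed model per variable,
#' \deqn{\log_{10} Y = a\, t_{age} (+ ROI\ terms) + u_{sample:ROI} +
#'   \epsilon,\qquad u \sim N(0, \sigma_{Sample}^2),\ \epsilon \sim
#'   N(0, \sigma_{Natural}^2),}
#' fit by REML (one shared age slope across samples; per-(sample, ROI)
#' random intercepts).  Harmonizing subtracts the predicted random intercept
#' (a BLUP, i.e. a shrinkage estimate) from each observation on the log
#' scale.  By default only healthy-control rows inform the fit; all groups
#' are then shifted with the control-derived offsets of their sample.
#'
#' @name harmonization
NULL

# map a user-facing variable name to the records column
variable_column <- function(variable) {
  switch(variable,
         T = "avg_thickness_mm", A_T = "total_area_mm2",
         A_E = "exposed_area_mm2", GI = "GI",
         K = "K", S = "S", I = "I",
         variable)
}

# log10 for the primary (positive, natural-scale) variables; identity for
# variables already on an additive scale (K, S, I and pre-logged columns)
variable_is_logged <- function(variable)
  variable %in% c("T", "A_T", "A_E", "GI")

extract_response <- function(records, variable) {
  col <- variable_column(variable)
  stopifnot_cols(records, col, "records")
  y <- records[[col]]
  if (variable_is_logged(variable)) {
    if (any(y <= 0)) stop("variable ", variable, " must be positive to log")
    y <- log10(y)
  }
  y
}

#' Fit the joint age trend with per-(sample, ROI) random intercepts
#'
#' @param records morphometric data.frame (see [read_morph_table()]).
#' @param variable one of `"T"`, `"A_T"`, `"A_E"`, `"GI"`, `"K"`, `"S"`,
#'   `"I"` or a raw column name.  Primary variables are modeled on the
#'   log10 scale.
#' @param use_roi_interaction include ROI main effect and Age x ROI
#'   interaction as fixed terms (only meaningful with > 1 ROI present).
#' @param groups_for_fit diagnostic labels whose rows inform the fit
#'   (default `"CTL"`); `NULL` uses all rows.
#' @return a `harmonization_fit`: list with `variable`, `slope` (named per
#'   ROI), `intercept` (named per ROI, age-0 value), `random_intercepts`
#'   (data.frame sample/roi/b), `sigma_residual`, `sigma_sample`, `n_obs`,
#'   `boundary` (TRUE when the random-effect variance was estimated at 0 or
#'   the fit is singular), `single_sample` flag, and the underlying `model`.
#' @export
fit_joint_trend <- function(records, variable,
                            use_roi_interaction = FALSE,
                            groups_for_fit = "CTL") {
  stopifnot_cols(records, c("sample", "roi", "age_years"), "records")
  fit_rows <- if (is.null(groups_for_fit)) rep(TRUE, nrow(records))
              else records$group %in% groups_for_fit
  if (!any(fit_rows))
    stop("no rows in groups_for_fit (", paste(groups_for_fit, collapse = ","),
         ") to fit on")
  df <- records[fit_rows, , drop = FALSE]
  df$.y <- extract_response(df, variable)
  df$.cell <- interaction(df$sample, df$roi, sep = ":", drop = TRUE)
  n_roi <- length(unique(df$roi))
  n_sample <- length(unique(df$sample))
  if (length(unique(df$age_years)) < 3)
    stop("need >= 3 distinct ages to identify the age trend")

  use_roi <- use_roi_interaction && n_roi > 1
  cells <- unique(df[c("sample", "roi")])

  if (n_sample < 2) {
    # degenerate random part: plain OLS, offsets identically zero
    fml <- if (use_roi) .y ~ age_years * roi else .y ~ age_years
    m <- lm(fml, data = df)
    slopes <- roi_slopes(coef(m), unique(df$roi), use_roi)
    intercepts <- roi_intercepts(coef(m), unique(df$roi), use_roi)
    ri <- cells; ri$b <- 0
    fit <- list(variable = variable, slope = slopes, intercept = intercepts,
                slope_se = summary(m)$coefficients["age_years", 2],
                random_intercepts = ri,
                sigma_residual = summary(m)$sigma, sigma_sample = 0,
                n_obs = nrow(df), boundary = TRUE, single_sample = TRUE,
                use_roi_interaction = use_roi, model = m,
                groups_for_fit = groups_for_fit)
    return(structure(fit, class = "harmonization_fit"))
  }

  fml <- if (use_roi) .y ~ age_years * roi + (1 | .cell)
         else .y ~ age_years + (1 | .cell)
  m <- lme4::lmer(fml, data = df, REML = TRUE,
                  control = lme4::lmerControl(
                    check.conv.singular = "ignore",
                    optCtrl = list(xtol_abs = 1e-10, ftol_abs = 1e-10)))
  fe <- lme4::fixef(m)
  re <- lme4::ranef(m)$.cell
  key <- rownames(re)
  ri_map <- setNames(re[["(Intercept)"]], key)
  ri <- cells
  ri$b <- unname(ri_map[paste(ri$sample, ri$roi, sep = ":")])
  ri$b[is.na(ri$b)] <- 0
  vc <- as.data.frame(lme4::VarCorr(m))
  sigma_sample <- vc$sdcor[vc$grp == ".cell"]
  sigma_residual <- vc$sdcor[vc$grp == "Residual"]
  fit <- list(variable = variable,
              slope = roi_slopes(fe, unique(df$roi), use_roi),
              intercept = roi_intercepts(fe, unique(df$roi), use_roi),
              slope_se = coef(summary(m))["age_years", "Std. Error"],
              random_intercepts = ri,
              sigma_residual = sigma_residual,
              sigma_sample = sigma_sample,
              n_obs = nrow(df),
              boundary = lme4::isSingular(m) || sigma_sample < 1e-8,
              single_sample = FALSE,
              use_roi_interaction = use_roi, model = m,
              groups_for_fit = groups_for_fit)
  structure(fit, class = "harmonization_fit")
}

# assemble per-ROI slopes/intercepts from treatment-coded fixed effects
roi_slopes <- function(fe, rois, use_roi) {
  if (!use_roi) return(setNames(rep(unname(fe["age_years"]), length(rois)),
                                rois))
  out <- setNames(numeric(length(rois)), sort(rois))
  ref <- sort(rois)[1]
  for (r in names(out)) {
    extra <- fe[paste0("age_years:roi", r)]
    out[r] <- unname(fe["age_years"]) + ifelse(is.na(extra), 0, unname(extra))
  }
  out
}

roi_intercepts <- function(fe, rois, use_roi) {
  if (!use_roi) return(setNames(rep(unname(fe["(Intercept)"]), length(rois)),
                                rois))
  out <- setNames(numeric(length(rois)), sort(rois))
  for (r in names(out)) {
    extra <- fe[paste0("roi", r)]
    out[r] <- unname(fe["(Intercept)"]) + ifelse(is.na(extra), 0,
                                                 unname(extra))
  }
  out
}

#' @export
print.harmonization_fit <- function(x, ...) {
  cat(sprintf("Harmonization fit for %s (log10 scale: %s)\n", x$variable,
              variable_is_logged(x$variable)))
  cat(sprintf("  shared slope: %s per year\n",
              paste(sprintf("%s=%.3g", names(x$slope), x$slope),
                    collapse = ", ")))
  cat(sprintf("  sigma_residual = %.4g, sigma_sample = %.4g (n = %d)\n",
              x$sigma_residual, x$sigma_sample, x$n_obs))
  if (x$boundary) cat("  note: random-effect variance at boundary\n")
  invisible(x)
}

lookup_offsets <- function(fit, records, strict) {
  key_fit <- paste(fit$random_intercepts$sample, fit$random_intercepts$roi,
                   sep = ":")
  key_rec <- paste(records$sample, records$roi, sep = ":")
  idx <- match(key_rec, key_fit)
  if (anyNA(idx)) {
    unseen <- unique(key_rec[is.na(idx)])
    if (strict)
      stop("records from (sample:roi) cells unseen by the fit: ",
           paste(unseen, collapse = ", "), call. = FALSE)
    warning("passing through unseen cells unchanged: ",
            paste(unseen, collapse = ", "))
  }
  b <- fit$random_intercepts$b[idx]
  b[is.na(b)] <- 0
  b
}

#' Subtract the fitted sample shifts (harmonize)
#'
#' On the log10 scale, `value' = value - b_hat[sample, roi]`; for variables
#' modeled in natural units (K, S, I) the shift is subtracted directly.
#'
#' @param records morphometric data.frame.
#' @param fit a [fit_joint_trend()] result for the variable to harmonize.
#' @param strict error (rather than pass through) on (sample, roi) cells the
#'   fit has not seen.
#' @return `records` with the fitted variable's column shifted.
#' @export
harmonize <- function(records, fit, strict = TRUE) {
  stopifnot(inherits(fit, "harmonization_fit"))
  b <- lookup_offsets(fit, records, strict)
  col <- variable_column(fit$variable)
  idx <- b != 0     # zero shift is the exact identity, skip the transform
  if (variable_is_logged(fit$variable)) {
    records[[col]][idx] <- 10^(log10(records[[col]][idx]) - b[idx])
  } else {
    records[[col]][idx] <- records[[col]][idx] - b[idx]
  }
  records
}

#' Harmonize the three primary variables of a cohort
#'
#' Fits and subtracts sample shifts for T, A_T and A_E; K, S, I and GI are
#' intended to be recomputed from the harmonized primaries (they commute
#' with per-record linear shifts of the logs).
#'
#' @inheritParams fit_joint_trend
#' @param strict see [harmonize()].
#' @return list with `records` (harmonized) and `fits` (named list of
#'   `harmonization_fit`).
#' @export
harmonize_cohort <- function(records, use_roi_interaction = FALSE,
                             groups_for_fit = "CTL", strict = TRUE) {
  fits <- lapply(setNames(nm = c("T", "A_T", "A_E")), function(v)
    fit_joint_trend(records, v, use_roi_interaction, groups_for_fit))
  for (v in names(fits)) records <- harmonize(records, fits[[v]], strict)
  list(records = records, fits = fits)
}

#' Remove the fitted age trend (de-aging)
#'
#' Expresses every observation at a common reference age:
#' `value' = value - a_hat[roi] * (age - reference_age)` on the model scale.
#'
#' @inheritParams harmonize
#' @param reference_age_years reference age in years.
#' @return `records` with the fitted variable's column de-aged.
#' @export
deage <- function(records, fit, reference_age_years) {
  stopifnot(inherits(fit, "harmonization_fit"))
  slope <- fit$slope[records$roi]
  slope[is.na(slope)] <- fit$slope[1]
  shift <- unname(slope) * (records$age_years - reference_age_years)
  col <- variable_column(fit$variable)
  if (variable_is_logged(fit$variable)) {
    records[[col]] <- 10^(log10(records[[col]]) - shift)
  } else {
    records[[col]] <- records[[col]] - shift
  }
  records
}
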