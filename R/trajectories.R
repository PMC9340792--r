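#' Lifespan baselines, aging rates and group contrasts
#'
#' After harmonization, each variable's trend with age is summarized by a
#' per-(variable, group, ROI) least-squares line.  T, A_T and A_E are fit on
#' the (back-transformed) measurement scale so rates come out in mm/year
#' and mm^2/year; K, S, I and GI are fit in their natural (dimensionless)
#' units.  Group differences in aging rate are tested through the
#' Age x Group interaction (Wald t on the slope contrast, sign convention
#' AD - CTL, i.e. second level minus reference is reported as
#' `group2 - group1` with groups ordered as given), with optional
#' Bonferroni or Tukey family-wise adjustment.
#'
#' @name trajectories
NULL

#' Per-cell age trends
#'
#' @param records harmonized, folding-augmented data.frame (see
#'   [add_folding_coords()]).
#' @param variables variable names to fit (`"T"`, `"A_T"`, `"A_E"`, `"GI"`,
#'   `"K"`, `"S"`, `"I"` or raw columns).
#' @param groups diagnostic labels to fit (default: all present).
#' @param rois ROI labels to fit (default: all present).
#' @param reference_age_years age at which `percent_per_year` is evaluated
#'   (slope / fitted value at that age x 100); default: the grand mean age
#'   of the `CTL` rows (or of all rows when no CTL present).
#' @param log_scale_rates fit the primary variables on the log10 scale and
#'   report `slope * ln(10) * fitted value` instead of the direct
#'   natural-scale slope (first-order equivalent alternative).
#' @return data.frame (class `trajectory_fits`) with one row per fitted
#'   cell: `variable`, `group`, `roi`, `slope`, `slope_se`, `ci_lo`,
#'   `ci_hi`, `intercept`, `percent_per_year`, `n`; skipped degenerate
#'   cells are listed in attribute `skipped`.
#' @export
fit_trajectories <- function(records, variables = c("K", "S", "I"),
                             groups = NULL, rois = NULL,
                             reference_age_years = NULL,
                             log_scale_rates = FALSE) {
  stopifnot_cols(records, c("group", "roi", "age_years"), "records")
  groups <- groups %||% unique(records$group)
  rois <- rois %||% unique(records$roi)
  if (is.null(reference_age_years)) {
    ctl <- records$age_years[records$group == "CTL"]
    reference_age_years <- if (length(ctl)) mean(ctl)
                           else mean(records$age_years)
  }
  out <- list(); skipped <- character(0)
  for (v in variables) for (g in groups) for (r in rois) {
    sel <- records$group == g & records$roi == r
    cell <- records[sel, , drop = FALSE]
    if (nrow(cell) < 3 || length(unique(cell$age_years)) < 3) {
      skipped <- c(skipped, sprintf("%s/%s/%s (n=%d, %d distinct ages)",
                                    v, g, r, nrow(cell),
                                    length(unique(cell$age_years))))
      next
    }
    y <- cell[[variable_column(v)]]
    use_log <- log_scale_rates && variable_is_logged(v)
    if (use_log) y <- log10(y)
    m <- lm(y ~ age_years, data = data.frame(y = y,
                                             age_years = cell$age_years))
    sm <- summary(m)$coefficients
    slope <- sm["age_years", 1]; se <- sm["age_years", 2]
    fit_ref <- unname(coef(m)[1] + coef(m)[2] * reference_age_years)
    if (use_log) {
      # d(10^y)/dt = ln10 * 10^y * dy/dt evaluated at the reference age
      val_ref <- 10^fit_ref
      slope_nat <- log(10) * val_ref * slope
      se_nat <- log(10) * val_ref * se
      pct <- 100 * slope * log(10)
      row <- data.frame(variable = v, group = g, roi = r,
                        slope = slope_nat, slope_se = se_nat,
                        intercept = unname(coef(m)[1]),
                        percent_per_year = pct, n = nrow(cell))
    } else {
      # divide by |fitted value| so the rate keeps the slope's sign even
      # for variables whose baseline is negative (K is a log)
      pct <- if (fit_ref != 0) 100 * slope / abs(fit_ref) else NA_real_
      row <- data.frame(variable = v, group = g, roi = r, slope = slope,
                        slope_se = se, intercept = unname(coef(m)[1]),
                        percent_per_year = pct, n = nrow(cell))
    }
    tq <- qt(0.975, df = nrow(cell) - 2)
    row$ci_lo <- row$slope - tq * row$slope_se
    row$ci_hi <- row$slope + tq * row$slope_se
    out[[length(out) + 1L]] <- row
  }
  if (length(skipped))
    warning("skipped degenerate cell(s): ", paste(skipped, collapse = "; "))
  res <- if (length(out)) do.call(rbind, out) else
    data.frame(variable = character(0))
  attr(res, "reference_age_years") <- reference_age_years
  attr(res, "skipped") <- skipped
  class(res) <- c("trajectory_fits", "data.frame")
  res
}

#' Pairwise slope contrasts between diagnostic groups
#'
#' Fits `value ~ age * group` (per ROI, or `value ~ age * group * roi` with
#' a `(1 | sample:group:roi)` random intercept when `by_roi = TRUE` and
#' several samples are present) and compares per-group age slopes with
#' [emmeans::emtrends()].  The contrast sign is `first level - second
#' level` with groups ordered as supplied, so the default `groups =
#' c("AD", "CTL")` reports AD - CTL.
#'
#' @param records harmonized, folding-augmented data.frame.
#' @param variable one variable name.
#' @param groups group labels (order fixes the contrast sign).
#' @param roi single ROI to analyze (ignored when `by_roi = TRUE`).
#' @param by_roi estimate one contrast per ROI from a joint
#'   Age x Group x ROI model.
#' @param adjust `"none"`, `"bonferroni"` or `"tukey"`.
#' @param use_random include the per-(sample, group, roi) random intercept
#'   in the `by_roi` model when > 1 sample is present.
#' @return data.frame (class `slope_contrasts`): `variable`, `roi`,
#'   `contrast`, `estimate` (slope difference per year), `se`, `df`,
#'   `p_value`, `p_adjusted`, `adjust`.
#' @export
compare_slopes <- function(records, variable, groups = c("AD", "CTL"),
                           roi = "hemisphere", by_roi = FALSE,
                           adjust = c("none", "bonferroni", "tukey"),
                           use_random = TRUE) {
  adjust <- match.arg(adjust)
  keep <- records$group %in% groups
  if (!by_roi) keep <- keep & records$roi == roi
  df <- records[keep, , drop = FALSE]
  if (length(unique(df$group)) < 2)
    stop("need >= 2 groups with data for a slope contrast")
  df$.y <- df[[variable_column(variable)]]
  df$group <- factor(df$group, levels = groups)
  if (by_roi && length(unique(df$roi)) > 1) {
    df$roi <- factor(df$roi)
    many_samples <- length(unique(df$sample)) > 1
    if (use_random && many_samples) {
      df$.cell <- interaction(df$sample, df$group, df$roi, drop = TRUE)
      m <- lme4::lmer(.y ~ age_years * group * roi + (1 | .cell), data = df,
                      REML = TRUE,
                      control = lme4::lmerControl(check.conv.singular =
                                                    "ignore"))
    } else {
      m <- lm(.y ~ age_years * group * roi, data = df)
    }
    emt <- emmeans::emtrends(m, ~ group | roi, var = "age_years",
                             lmer.df = "asymptotic")
  } else {
    m <- lm(.y ~ age_years * group, data = df)
    emt <- emmeans::emtrends(m, ~ group, var = "age_years")
  }
  prs <- summary(emmeans::contrast(emt, method = "pairwise",
                                   adjust = if (adjust == "tukey") "tukey"
                                            else "none"))
  res <- data.frame(variable = variable,
                    roi = if ("roi" %in% names(prs)) as.character(prs$roi)
                          else roi,
                    contrast = as.character(prs$contrast),
                    estimate = prs$estimate, se = prs$SE,
                    df = prs$df,
                    p_value = NA_real_, p_adjusted = prs$p.value,
                    adjust = adjust, row.names = NULL)
  # unadjusted p for reference; for tukey emmeans already adjusted above
  un <- summary(emmeans::contrast(emt, method = "pairwise", adjust = "none"))
  res$p_value <- un$p.value
  if (adjust == "bonferroni")
    res$p_adjusted <- pmin(1, res$p_value * nrow(res))
  if (adjust == "none") res$p_adjusted <- res$p_value
  res$p_adjusted <- pmax(res$p_adjusted, res$p_value)
  class(res) <- c("slope_contrasts", "data.frame")
  res
}

#' Self-similarity exponent per decade of age
#'
#' Bins ages into [0,10), [10,20), ... and fits [fit_alpha()] per bin and
#' group; bins with fewer than `min_n` observations are omitted and listed.
#'
#' @param records morphometric data.frame (whole-hemisphere rows are used
#'   unless `roi` says otherwise).
#' @param min_n minimum observations per bin (default 10).
#' @param groups group labels (default: all present).
#' @param roi ROI to analyze.
#' @return data.frame (class `alpha_by_decade`): `group`, `bin_low`,
#'   `bin_high`, `n`, `alpha`, `ci_lo`, `ci_hi`, `r2`; omitted bins in
#'   attribute `omitted` (data.frame `group`, `bin_low`, `bin_high`, `n`).
#' @export
alpha_by_decade <- function(records, min_n = 10, groups = NULL,
                            roi = "hemisphere") {
  if ("roi" %in% names(records))
    records <- records[records$roi == roi, , drop = FALSE]
  if (!nrow(records)) stop("no records to bin")
  groups <- groups %||% unique(records$group)
  edges <- seq(0, 120, by = 10)
  out <- list(); omitted <- list()
  for (g in groups) {
    sub <- records[records$group == g, , drop = FALSE]
    bin <- findInterval(sub$age_years, edges, rightmost.closed = TRUE)
    for (k in sort(unique(bin))) {
      cell <- sub[bin == k, , drop = FALSE]
      lohi <- c(edges[k], edges[k + 1])
      if (nrow(cell) < min_n ||
          length(unique(cell$exposed_area_mm2)) < 3) {
        omitted[[length(omitted) + 1L]] <-
          data.frame(group = g, bin_low = lohi[1], bin_high = lohi[2],
                     n = nrow(cell))
        next
      }
      f <- fit_alpha(cell)
      out[[length(out) + 1L]] <-
        data.frame(group = g, bin_low = lohi[1], bin_high = lohi[2],
                   n = f$n, alpha = f$alpha, ci_lo = f$ci95_alpha[1],
                   ci_hi = f$ci95_alpha[2], r2 = f$r2)
    }
  }
  res <- if (length(out)) do.call(rbind, out) else
    data.frame(group = character(0))
  attr(res, "omitted") <- if (length(omitted)) do.call(rbind, omitted) else
    data.frame(group = character(0), bin_low = numeric(0),
               bin_high = numeric(0), n = integer(0))
  attr(res, "min_n") <- min_n
  class(res) <- c("alpha_by_decade", "data.frame")
  res
}

#' Normative baseline bands
#'
#' Joins trajectory fits with uncertainty budgets: the baseline at age t is
#' `intercept + slope * t`, the normative band that value +/- `sigma_total`.
#'
#' @param fits a [fit_trajectories()] result.
#' @param budgets named list of [build_budget()] results (names are
#'   variable labels).
#' @return data.frame (class `baseline_table`): the fit columns plus
#'   `sigma_total` (NA, with a `missing_budget` flag, for variables without
#'   a budget).
#' @export
baseline_table <- function(fits, budgets) {
  stopifnot(inherits(fits, "trajectory_fits"))
  if (length(budgets) && is.null(names(budgets)))
    stop("budgets must be a named list (variable -> budget)")
  bvars <- names(budgets)
  extra <- setdiff(bvars, unique(fits$variable))
  if (length(extra))
    stop("budget variable(s) without a trajectory fit: ",
         paste(extra, collapse = ", "))
  st <- vapply(as.character(fits$variable), function(v)
    if (v %in% bvars) budgets[[v]]$sigma_total else NA_real_, numeric(1))
  out <- fits
  out$sigma_total <- st
  out$missing_budget <- is.na(st)
  class(out) <- c("baseline_table", class(fits))
  out
}

#' Evaluate a baseline band at given ages
#'
#' @param baseline a [baseline_table()] result.
#' @param variable,group,roi cell selector.
#' @param ages ages (years) at which to evaluate.
#' @return data.frame `age`, `value`, `lo`, `hi` (lo/hi are NA without a
#'   budget).
#' @export
baseline_band <- function(baseline, variable, group, roi, ages) {
  row <- baseline[baseline$variable == variable & baseline$group == group &
                    baseline$roi == roi, , drop = FALSE]
  if (nrow(row) != 1) stop("cell not found (or not unique) in baseline table")
  val <- row$intercept + row$slope * ages
  data.frame(age = ages, value = val,
             lo = val - row$sigma_total, hi = val + row$sigma_total)
}
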