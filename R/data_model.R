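#' Long-format morphometric tables
#'
#' One row per subject x hemisphere x region of interest, the shape produced
#' by FreeSurfer-based extraction tools.  Canonical columns (units fixed
#' here, everywhere):
#' `subject_id`, `sample` (site/cohort label), `group` (diagnostic, e.g.
#' `CTL`/`AD`), `sex` (`F`/`M`/`unknown`), `age_years`, `hemisphere`
#' (`left`/`right`), `roi` (`hemisphere`, `frontal`, `temporal`, `parietal`,
#' `occipital`; `lateral` is accepted on input as an alias of `parietal`),
#' `avg_thickness_mm` (> 0), `total_area_mm2` (> 0), `exposed_area_mm2`
#' (> 0) and optional `local_gi` (> 0).
#'
#' Hard invariants: positive T/A_T/A_E (their logs must exist), ages within
#' 0-120 years, and for whole-hemisphere rows total area at least the exposed
#' area (a folded surface exceeds its hull).  For lobes the area ordering is
#' only warned about, since curvature-corrected lobe areas may deviate.
#'
#' @name morph_table
NULL

MORPH_COLS <- c("subject_id", "sample", "group", "sex", "age_years",
                "hemisphere", "roi", "avg_thickness_mm", "total_area_mm2",
                "exposed_area_mm2")
MORPH_COLS_OPT <- "local_gi"
ROI_LEVELS <- c("hemisphere", "frontal", "temporal", "parietal", "occipital")

#' Validate a morphometric table
#'
#' @param df data.frame with (at least) the canonical columns.
#' @param strict if `TRUE`, any hard-invariant violation is an error; if
#'   `FALSE`, offending rows are dropped and counted in the report.
#' @return the validated (possibly row-filtered) data.frame with a
#'   `validation_report` attribute: a list with `n_input`, `n_kept`,
#'   `n_rejected`, `rejections` (data.frame row/reason) and `warnings`.
#' @export
validate_morph_table <- function(df, strict = TRUE) {
  stopifnot_cols(df, MORPH_COLS, "morphometric table")
  df$roi <- ifelse(tolower(df$roi) == "lateral", "parietal", tolower(df$roi))
  df$hemisphere <- tolower(df$hemisphere)

  reasons <- character(0); rows <- integer(0)
  flag <- function(bad, why) {
    bad[is.na(bad)] <- TRUE
    rows <<- c(rows, which(bad)); reasons <<- c(reasons, rep(why, sum(bad)))
  }
  flag(!(df$avg_thickness_mm > 0), "non-positive thickness")
  flag(!(df$total_area_mm2 > 0), "non-positive area (total)")
  flag(!(df$exposed_area_mm2 > 0), "non-positive area (exposed)")
  flag(!(df$age_years >= 0 & df$age_years <= 120), "age outside [0, 120]")
  flag(!(df$roi %in% ROI_LEVELS), "unknown roi")
  flag(!(df$hemisphere %in% c("left", "right")), "unknown hemisphere")
  hemi_bad <- df$roi == "hemisphere" &
    !is.na(df$total_area_mm2) & !is.na(df$exposed_area_mm2) &
    df$total_area_mm2 < df$exposed_area_mm2
  flag(hemi_bad, "total area below exposed area for hemisphere roi")

  warnings <- character(0)
  lobe_odd <- df$roi != "hemisphere" & df$total_area_mm2 < df$exposed_area_mm2
  if (any(lobe_odd, na.rm = TRUE))
    warnings <- c(warnings, sprintf(
      "%d lobe row(s) with total area below exposed area (allowed: curvature-corrected lobe areas may deviate)",
      sum(lobe_odd, na.rm = TRUE)))

  rej <- data.frame(row = rows, reason = reasons)
  rej <- rej[!duplicated(rej$row), , drop = FALSE]
  if (nrow(rej) && strict)
    stop("invalid morphometric rows (strict mode): ",
         paste(sprintf("row %d: %s", rej$row, rej$reason), collapse = "; "),
         call. = FALSE)
  keep <- setdiff(seq_len(nrow(df)), rej$row)
  out <- df[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "validation_report") <- list(
    n_input = nrow(df), n_kept = length(keep), n_rejected = nrow(rej),
    rejections = rej, warnings = warnings)
  out
}

#' Accessor for the validation report attached by read/validate
#' @param records a table returned by [read_morph_table()] or
#'   [validate_morph_table()].
#' @return the report list (see [validate_morph_table()]).
#' @export
validation_report <- function(records) attr(records, "validation_report")

#' Read a long-format morphometric CSV
#'
#' Comma-separated, UTF-8, `.` decimal, header required; column names are
#' matched case-insensitively and reordered to the canonical schema.
#'
#' @param path CSV file path.
#' @param strict see [validate_morph_table()].
#' @return validated data.frame with a `validation_report` attribute.
#' @export
read_morph_table <- function(path, strict = TRUE) {
  df <- read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  names(df) <- tolower(trimws(names(df)))
  stopifnot_cols(df, MORPH_COLS, basename(path))
  keep <- c(MORPH_COLS, intersect(MORPH_COLS_OPT, names(df)))
  validate_morph_table(df[keep], strict = strict)
}

#' Write a morphometric table to CSV
#'
#' Values are written with 15 significant digits so that
#' `read_morph_table(write_morph_table(x, f))` round-trips numerics to
#' better than 1e-9 relative.  An all-`NA` `local_gi` column is omitted.
#'
#' @param records validated morphometric data.frame.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_morph_table <- function(records, path) {
  cols <- c(MORPH_COLS, intersect(MORPH_COLS_OPT, names(records)))
  out <- records[cols]
  if ("local_gi" %in% names(out) && all(is.na(out$local_gi)))
    out$local_gi <- NULL
  num <- vapply(out, is.numeric, logical(1))
  out[num] <- lapply(out[num], function(v) {
    s <- formatC(v, digits = 15, format = "g")
    s[is.na(v)] <- NA_character_
    s
  })
  write.csv(out, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' Age intervals and age resolution
#'
#' Some cohorts report an age range rather than an exact age; the convention
#' is to use the interval midpoint as the reference age.
#'
#' @param low_years,high_years interval bounds in years, `low < high`.
#' @return an `age_interval` object.
#' @export
age_interval <- function(low_years, high_years) {
  if (!is.finite(low_years) || !is.finite(high_years) ||
      low_years >= high_years)
    stop("age interval requires finite low < high")
  structure(list(low_years = low_years, high_years = high_years),
            class = "age_interval")
}

#' Resolve an exact age or an age interval to a single reference age
#'
#' Exact ages pass through unchanged; an [age_interval()] maps to its
#' midpoint `(low + high) / 2`.
#'
#' @param age a non-negative numeric age in years, or an `age_interval`.
#' @return numeric age in years.
#' @export
resolve_age <- function(age) UseMethod("resolve_age")

#' @export
resolve_age.numeric <- function(age) {
  if (any(!is.finite(age) | age < 0)) stop("age must be finite and >= 0")
  age
}

#' @export
resolve_age.age_interval <- function(age)
  (age$low_years + age$high_years) / 2

#' Collapse left/right hemisphere rows by averaging (optional pre-step)
#'
#' Averages `avg_thickness_mm`, `total_area_mm2`, `exposed_area_mm2` (and
#' `local_gi` when present) over hemispheres within
#' (subject, sample, group, roi).  Off by default in every pipeline: the
#' standard analysis treats each hemisphere as one observation.
#'
#' @param records validated morphometric data.frame.
#' @return data.frame with one row per (subject, sample, group, roi) and
#'   `hemisphere = "both"`.
#' @export
average_hemispheres <- function(records) {
  key <- interaction(records$subject_id, records$sample, records$group,
                     records$roi, drop = TRUE)
  num_cols <- c("age_years", "avg_thickness_mm", "total_area_mm2",
                "exposed_area_mm2", intersect("local_gi", names(records)))
  agg <- stats::aggregate(records[num_cols], by = list(.key = key), FUN = mean)
  meta <- records[match(agg$.key, key),
                  c("subject_id", "sample", "group", "sex", "roi")]
  out <- cbind(meta, hemisphere = "both", agg[num_cols])
  rownames(out) <- NULL
  out[c("subject_id", "sample", "group", "sex", "age_years", "hemisphere",
        "roi", num_cols[num_cols != "age_years"])]
}
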