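#' Pipeline orchestration
#'
#' `run_pipeline()` executes the full analysis chain on a synthetic cohort:
#' simulate -> folding coordinates -> harmonize -> uncertainty budget ->
#' trend-model selection -> trajectories, writing every stage's output to
#' an artifact directory together with a manifest (config echo, seed,
#' package version, per-file checksums).  Re-running with an identical
#' config reproduces every CSV/JSON byte-identically.
#'
#' @name cli_config
NULL

#' Default pipeline configuration
#'
#' @param seed root seed for all stochastic stages.
#' @param out_dir artifact directory.
#' @return a `run_config` list; fields may be edited before
#'   [run_pipeline()].
#' @export
default_config <- function(seed = 1L, out_dir = tempfile("foldbase_run_")) {
  structure(list(
    seed = as.integer(seed),
    out_dir = out_dir,
    s_variant = "orthogonal",
    cohort = list(generation_mode = "ksi_latent", n_per_sample = 150,
                  include_ad = TRUE),
    harmonization = list(use_roi_interaction = FALSE,
                         groups_for_fit = "CTL"),
    repeats = list(n_repeats = 3, n_subjects = 50),
    evidence = list(enable = TRUE, variable = "T",
                    models = c("base", "i", "ii", "iii", "iv"),
                    n_nodes = 32),
    trajectories = list(variables = c("K", "S", "I", "T", "GI"),
                        adjust = "tukey", min_n = 10)),
    class = "run_config")
}

#' Read a pipeline configuration from YAML
#'
#' Fields missing from the file keep the [default_config()] values.
#'
#' @param path YAML file.
#' @return a `run_config`.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  user <- yaml::read_yaml(path)
  cfg <- default_config()
  for (k in names(user)) {
    if (is.list(user[[k]]) && is.list(cfg[[k]]))
      cfg[[k]] <- utils::modifyList(cfg[[k]], user[[k]])
    else cfg[[k]] <- user[[k]]
  }
  cfg$seed <- as.integer(cfg$seed)
  cfg
}

pipeline_cohort_spec <- function(config) {
  mode <- config$cohort$generation_mode %||% "ksi_latent"
  groups <- default_group_params(mode)
  if (!isTRUE(config$cohort$include_ad) || mode == "log_linear")
    groups <- groups["CTL"]
  cohort_spec(
    samples = default_samples(config$cohort$n_per_sample %||% 150),
    groups = groups,
    generation_mode = mode,
    s_variant = config$s_variant %||% "orthogonal",
    seed = config$seed)
}

#' Run the full pipeline
#'
#' @param config a `run_config` from [default_config()] or [read_config()].
#' @return (invisibly) the manifest list; artifacts land in
#'   `config$out_dir`.
#' @export
run_pipeline <- function(config = default_config()) {
  stopifnot(is.list(config), !is.null(config$seed), !is.null(config$out_dir))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  out <- function(f) file.path(config$out_dir, f)
  log_line <- function(stage, ...) message(sprintf("[foldbase] %-12s %s",
                                                  stage, sprintf(...)))
  notes <- character(0)

  # 1. simulate
  spec <- pipeline_cohort_spec(config)
  sim <- generate_cohort(spec)
  log_line("simulate", "%d records, %d samples, mode=%s, seed=%d",
           nrow(sim$records), nrow(spec$samples), spec$generation_mode,
           spec$seed)
  write_morph_table(sim$records, out("cohort.csv"))
  write_json_plain(list(offsets = sim$truth$offsets,
                        sigma_natural = sim$truth$sigma_natural,
                        sigma_random = sim$truth$sigma_random,
                        sigma_sample = sim$truth$sigma_sample,
                        generation_mode = sim$truth$generation_mode,
                        seed = sim$truth$seed), out("truth.json"))

  # 2. folding coordinates
  aug <- add_folding_coords(sim$records, config$s_variant)
  log_line("ksi", "s_variant=%s", config$s_variant)

  # 3. harmonize the primaries, recompute K/S/I/GI from harmonized values
  h <- harmonize_cohort(sim$records,
                        use_roi_interaction =
                          isTRUE(config$harmonization$use_roi_interaction),
                        groups_for_fit = config$harmonization$groups_for_fit)
  harmonized <- add_folding_coords(h$records, config$s_variant)
  for (v in names(h$fits))
    if (h$fits[[v]]$boundary)
      notes <- c(notes, sprintf("harmonization fit for %s at variance boundary", v))
  log_line("harmonize", "slopes: %s",
           paste(sprintf("%s=%.3g", names(h$fits),
                         vapply(h$fits, function(f) f$slope[[1]],
                                numeric(1))), collapse = ", "))
  write_morph_table(h$records, out("harmonized.csv"))
  fit_json <- lapply(h$fits, function(f)
    list(variable = f$variable, slope = as.list(f$slope),
         intercept = as.list(f$intercept),
         random_intercepts = f$random_intercepts,
         sigma_residual = f$sigma_residual, sigma_sample = f$sigma_sample,
         n_obs = f$n_obs, boundary = f$boundary))
  write_json_plain(fit_json, out("harmonization_fits.json"))

  # 4. uncertainty budgets
  repeats <- generate_repeats(spec,
                              n_repeats = config$repeats$n_repeats %||% 3,
                              n_subjects = config$repeats$n_subjects %||% 50)
  budget_vars <- intersect(config$trajectories$variables,
                           c("T", "A_T", "A_E", "GI", "K", "S", "I"))
  budgets <- list()
  for (v in budget_vars) {
    sr <- repeated_measures_sd(repeats, v, s_variant = config$s_variant)
    # variance components come from fits on the unharmonized table (the
    # harmonized one has its sample shifts removed by construction)
    fit_v <- if (v %in% names(h$fits)) h$fits[[v]]
             else fit_joint_trend(aug, v,
                                  groups_for_fit =
                                    config$harmonization$groups_for_fit)
    budgets[[v]] <- build_budget(fit_v, sr,
                                 reference_intercept = fit_v$intercept[[1]])
  }
  log_line("uncertainty", "sigma_total: %s",
           paste(sprintf("%s=%.3g", names(budgets),
                         vapply(budgets, `[[`, numeric(1), "sigma_total")),
                 collapse = ", "))
  write_json_plain(lapply(budgets, unclass), out("budget.json"))

  # 5. trend-model selection on the pooled CTL log10 trend
  if (isTRUE(config$evidence$enable)) {
    ctl <- sim$records[sim$records$group == "CTL", , drop = FALSE]
    ev_data <- morph_to_evidence_data(ctl, config$evidence$variable)
    evs <- lapply(config$evidence$models, function(mid)
      log_marginal_likelihood(mid, ev_data,
                              n_nodes = config$evidence$n_nodes %||% 32))
    ranking <- compare_models(evs)
    log_line("select-model", "winner=%s (p=%.3f)", ranking$model[1],
             ranking$posterior_prob[1])
    write_json_plain(ranking, out("evidence.json"))
  } else ranking <- NULL

  # 6. trajectories, contrasts, per-decade alpha
  fits <- fit_trajectories(harmonized,
                           variables = config$trajectories$variables)
  groups_present <- unique(harmonized$group)
  contrasts <- NULL
  if (all(c("CTL", "AD") %in% groups_present)) {
    contrasts <- do.call(rbind, lapply(
      intersect(config$trajectories$variables, c("K", "S", "I")),
      function(v) compare_slopes(harmonized, v, groups = c("AD", "CTL"),
                                 adjust = config$trajectories$adjust)))
  }
  abd <- alpha_by_decade(harmonized,
                         min_n = config$trajectories$min_n %||% 10)
  bl <- baseline_table(fits, budgets[intersect(names(budgets),
                                               unique(fits$variable))])
  log_line("trajectories", "%d cells fit, %d decade bins", nrow(fits),
           nrow(abd))
  write_json_plain(list(
    reference_age_years = attr(fits, "reference_age_years"),
    trajectories = as.data.frame(fits),
    contrasts = if (is.null(contrasts)) NULL else as.data.frame(contrasts),
    alpha_by_decade = as.data.frame(abd),
    alpha_omitted_bins = attr(abd, "omitted"),
    baselines = as.data.frame(bl)), out("trajectories.json"))

  files <- sort(list.files(config$out_dir, recursive = TRUE))
  files <- setdiff(files, "manifest.json")
  manifest <- list(
    package = "foldbase",
    version = as.character(utils::packageVersion("foldbase")),
    seed = config$seed,
    config = config[setdiff(names(config), "out_dir")],
    warnings = notes,
    files = data.frame(
      file = files,
      md5 = unname(tools::md5sum(file.path(config$out_dir, files)))))
  write_json_plain(manifest, out("manifest.json"))
  log_line("done", "%d artifacts in %s", length(files) + 1, config$out_dir)
  invisible(manifest)
}
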