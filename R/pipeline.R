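#' Read a signed effect-size vector from a two-column TSV
#'
#' @param path TSV with columns `phenotype` and `effect` (signed standardized
#'   case-control effects; deficits negative).
#' @return Tibble (`phenotype`, `effect`).
#' @export
read_effect_vector <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("Effect-vector file not found: ", path),
          class = "brainvuln_validation_error")
  }
  ev <- readr::read_tsv(path, comment = "#", show_col_types = FALSE,
                        progress = FALSE)
  if (!all(c("phenotype", "effect") %in% names(ev))) {
    abort(paste0("Effect-vector file must have columns `phenotype` and `effect`: ",
                 path),
          class = "brainvuln_validation_error")
  }
  ev
}

#' Pipeline configuration
#'
#' Bundles everything [run_pipeline()] needs. Exactly one of `cohort` (a
#' [cohort_config()] for the synthetic generator) or `input_dir` (a directory
#' of the five input tables as written by [write_cohort()]) must be given.
#'
#' @param cohort A [cohort_config()] (or argument list for one), or `NULL`.
#' @param input_dir Directory with `phenotypes.tsv`, `covariates.tsv`,
#'   `labels.tsv`, `cognition.tsv` (+ `tissue_map.tsv`), or `NULL`.
#' @param effect_vector Tibble or TSV path of signed effects; defaults to the
#'   cohort's planted vector when simulating.
#' @param covariate_set Covariates regressed in harmonization.
#' @param reference Harmonization reference sample, `"all"` or `"controls"`.
#' @param blom_offset Blom constant for the inverse-normal transform.
#' @param icv_volumes_only Restrict ICV adjustment to volume phenotypes.
#' @param qri_by_sex Fit quantile lines within sex strata.
#' @param biomarkers Biomarkers carried through the analyses.
#' @param profile_biomarkers Biomarkers given cognition profiles.
#' @param seed Integer seed for the whole run (overrides the cohort seed).
#' @param figures Write figure files.
#' @param verbose Emit progress messages.
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(cohort = cohort_config(), input_dir = NULL,
                            effect_vector = NULL,
                            covariate_set = c("age", "sex", "icv"),
                            reference = "all", blom_offset = 3 / 8,
                            icv_volumes_only = FALSE, qri_by_sex = FALSE,
                            biomarkers = c("edp", "qri_whole",
                                           "mean_thickness_z",
                                           "mean_subcort_z", "mean_fa_z"),
                            profile_biomarkers = c("edp", "qri_whole",
                                                   "mean_thickness_z",
                                                   "mean_subcort_z",
                                                   "mean_fa_z"),
                            seed = NULL, figures = FALSE, verbose = FALSE) {
  if (is.null(cohort) == is.null(input_dir)) {
    abort("Provide exactly one of `cohort` or `input_dir`.",
          class = "brainvuln_validation_error")
  }
  if (!is.null(cohort)) {
    if (!inherits(cohort, "cohort_config")) cohort <- do.call(cohort_config, cohort)
    if (!is.null(seed)) cohort$seed <- as.integer(seed)
    seed <- cohort$seed
  }
  structure(list(cohort = cohort, input_dir = input_dir,
                 effect_vector = effect_vector,
                 covariate_set = covariate_set, reference = reference,
                 blom_offset = blom_offset,
                 icv_volumes_only = icv_volumes_only,
                 qri_by_sex = qri_by_sex, biomarkers = biomarkers,
                 profile_biomarkers = profile_biomarkers,
                 seed = seed %||% NA_integer_, figures = figures,
                 verbose = verbose),
            class = "pipeline_config")
}

#' Run the vulnerability-index pipeline end to end
#'
#' Stages: `simulate` (or load the input tables), `harmonize` (residualize +
#' inverse-normal transform), `edp` (dot-product index and whole-brain
#' means), `qri` (normative quantile scoring), `analyze` (group-severity and
#' cognition pattern analyses). Every stage writes its outputs under
#' `outdir`, and any later stage can resume from those files, so re-running a
#' subset of stages never recomputes earlier ones. A rerun with an identical
#' config writes bit-identical tables.
#'
#' @param config A [pipeline_config()].
#' @param outdir Output directory.
#' @param stages Stages to run (in pipeline order).
#' @return The report (list), invisibly also written as `report.json`.
#' @export
run_pipeline <- function(config, outdir,
                         stages = c("simulate", "harmonize", "edp", "qri",
                                    "analyze")) {
  stopifnot(inherits(config, "pipeline_config"))
  stages <- match.arg(stages, several.ok = TRUE)
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  say <- function(...) if (isTRUE(config$verbose)) inform(paste0(...))
  warnings_log <- list()
  log_warning <- function(stage, msg) {
    warnings_log[[length(warnings_log) + 1L]] <<-
      list(stage = stage, message = msg)
  }
  with_logged_warnings <- function(stage, expr) {
    withCallingHandlers(expr, warning = function(w) {
      log_warning(stage, conditionMessage(w))
      invokeRestart("muffleWarning")
    })
  }
  cohort_dir <- file.path(outdir, "cohort")

  # -- inputs ---------------------------------------------------------------
  if ("simulate" %in% stages) {
    if (!is.null(config$cohort)) {
      say("simulate: generating synthetic cohort (seed ", config$cohort$seed, ")")
      cohort <- simulate_cohort(config$cohort)
      write_cohort(cohort, cohort_dir)
      inputs <- cohort[c("phenotypes", "covariates", "labels", "cognition")]
    } else {
      say("simulate: loading input tables from ", config$input_dir)
      for (f in c("phenotypes.tsv", "covariates.tsv", "labels.tsv",
                  "cognition.tsv")) {
        p <- file.path(config$input_dir, f)
        if (!file.exists(p)) {
          abort(paste0("[simulate] required input table not found: ", p),
                class = "brainvuln_validation_error")
        }
      }
      inputs <- read_cohort(config$input_dir)
    }
  } else {
    src <- if (!is.null(config$input_dir)) config$input_dir else cohort_dir
    inputs <- read_cohort(src)
  }
  tissue_map <- attr(inputs$phenotypes, "tissue_map") %||%
    default_phenotype_spec()

  effects <- config$effect_vector %||% config$cohort$effect_vector
  if (is.character(effects)) effects <- read_effect_vector(effects)
  if (is.null(effects)) {
    abort("[edp] no effect vector available: supply `effect_vector`.",
          class = "brainvuln_validation_error")
  }

  scores_path <- file.path(outdir, "subject_scores.tsv")
  z_path <- file.path(outdir, "zmatrix.tsv")

  # -- harmonize ------------------------------------------------------------
  if ("harmonize" %in% stages) {
    say("harmonize: ", config$reference, "-referenced Z matrix")
    z <- with_logged_warnings("harmonize",
      harmonize(inputs$phenotypes, inputs$covariates,
                covariate_set = config$covariate_set,
                reference = config$reference, labels = inputs$labels,
                blom_offset = config$blom_offset,
                icv_volumes_only = config$icv_volumes_only,
                tissue_map = tissue_map))
    write_zmatrix(z, z_path)
  } else if (file.exists(z_path)) {
    z <- read_tsv_exact(z_path)
    attr(z, "tissue_map") <- tissue_map
  } else z <- NULL

  read_scores <- function() {
    if (file.exists(scores_path))
      read_tsv_exact(scores_path)
    else NULL
  }

  # -- edp ------------------------------------------------------------------
  if ("edp" %in% stages) {
    if (is.null(z)) abort("[edp] no Z matrix: run or load the harmonize stage.",
                          class = "brainvuln_validation_error")
    say("edp: dot-product index over ", nrow(effects), " effects")
    scores <- with_logged_warnings("edp", {
      left_join(compute_edp(z, effects), whole_brain_means(z, tissue_map),
                by = "subject_id")
    })
    write_tsv_exact(scores, scores_path)
  } else scores <- read_scores()

  # -- qri ------------------------------------------------------------------
  qri_crossings <- 0L
  if ("qri" %in% stages) {
    say("qri: normative quantile scoring")
    qri <- with_logged_warnings("qri",
      compute_qri(inputs$phenotypes, inputs$covariates,
                  tissue_map = tissue_map, by_sex = config$qri_by_sex))
    qri_crossings <- nrow(qri$crossings)
    readr::write_tsv(tidy(qri$fits), file.path(outdir, "quantile_fits.tsv"))
    readr::write_tsv(qri$region_scores,
                     file.path(outdir, "qri_region_scores.tsv"))
    scores <- if (is.null(scores)) qri$scores
              else left_join(select(scores, -dplyr::any_of(
                     c("qri_thickness", "qri_subcort", "qri_fa", "qri_whole"))),
                   qri$scores, by = "subject_id")
    write_tsv_exact(scores, scores_path)
  } else scores <- scores %||% read_scores()

  # -- analyze --------------------------------------------------------------
  results <- NULL
  if ("analyze" %in% stages) {
    if (is.null(scores)) {
      abort("[analyze] no subject scores: run or load the edp/qri stages.",
            class = "brainvuln_validation_error")
    }
    say("analyze: group-severity and cognition pattern analyses")
    biomarkers <- intersect(config$biomarkers, names(scores))
    results <- with_logged_warnings("analyze", {
      gp <- group_profile(scores, inputs$covariates, inputs$labels,
                          biomarkers = biomarkers)
      gcors <- bind_rows(purrr::map(biomarkers,
                                    ~ groupmean_correlation(gp, .x)))
      assoc <- bind_rows(purrr::map(biomarkers, function(bm) {
        symptom_association(scores, inputs$covariates, inputs$labels, bm)
      }))
      deficit <- cognitive_deficit_profile(inputs$cognition, inputs$covariates,
                                           inputs$labels)
      prof_bms <- intersect(config$profile_biomarkers, names(scores))
      profiles <- list(mdd_vs_control = deficit)
      comparisons <- list()
      for (sub in c("controls", "depressed")) {
        for (bm in prof_bms) {
          pr <- biomarker_cognition_profile(scores, inputs$cognition,
                                            inputs$covariates, inputs$labels,
                                            biomarker = bm, subset = sub)
          profiles[[attr(pr, "profile")]] <- pr
          comparisons[[length(comparisons) + 1L]] <-
            compare_profiles(pr, deficit)
        }
      }
      list(group_summary = gp, groupmean_correlations = gcors,
           symptom_associations = assoc, profiles = profiles,
           profile_comparisons = bind_rows(comparisons))
    })
    readr::write_tsv(results$group_summary,
                     file.path(outdir, "group_summary.tsv"))
    readr::write_tsv(results$groupmean_correlations,
                     file.path(outdir, "groupmean_correlations.tsv"))
    readr::write_tsv(results$symptom_associations,
                     file.path(outdir, "symptom_associations.tsv"))
    readr::write_tsv(bind_rows(purrr::map(results$profiles, tidy)),
                     file.path(outdir, "association_profiles.tsv"))
    readr::write_tsv(results$profile_comparisons,
                     file.path(outdir, "profile_comparisons.tsv"))
    if (isTRUE(config$figures)) {
      write_pipeline_figures(results, outdir)
    }
  }

  report <- list(
    package_version = as.character(utils::packageVersion("brainvuln")),
    seed = config$seed,
    config_hash = digest::digest(config),
    stages = stages,
    n_subjects = nrow(inputs$covariates),
    n_phenotypes = ncol(inputs$phenotypes) - 1L,
    qri_crossings = qri_crossings,
    warnings = warnings_log,
    groupmean_correlations = if (!is.null(results))
      results$groupmean_correlations,
    symptom_associations = if (!is.null(results))
      results$symptom_associations,
    profile_comparisons = if (!is.null(results))
      results$profile_comparisons
  )
  jsonlite::write_json(report, file.path(outdir, "report.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA,
                       dataframe = "rows")
  invisible(report)
}

write_pipeline_figures <- function(results, outdir) {
  fig_dir <- file.path(outdir, "figures")
  dir.create(fig_dir, recursive = TRUE, showWarnings = FALSE)
  ggplot2::ggsave(file.path(fig_dir, "group_profile.png"),
                  plot_group_profile(results$group_summary),
                  width = 8, height = 5, dpi = 150)
  deficit <- results$profiles$mdd_vs_control
  for (nm in setdiff(names(results$profiles), "mdd_vs_control")) {
    ggplot2::ggsave(
      file.path(fig_dir, paste0("profile_", nm, ".png")),
      plot_profile_comparison(results$profiles[[nm]], deficit),
      width = 5, height = 5, dpi = 150)
  }
  invisible(fig_dir)
}
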