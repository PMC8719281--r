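#' Configuration for the synthetic cohort generator
#'
#' Bundles all generative parameters for [simulate_cohort()]. Defaults emulate
#' a population-imaging cohort stratified into four depression-severity groups
#' (control, subclinical, single-episode, recurrent) with a graded structural
#' deficit planted along a signed effect-size vector, linear age decline, sex
#' and head-size (ICV) effects, and cognitive scores coupled to the latent
#' vulnerability in a designated subset of tests.
#'
#' Planted effect magnitudes are deliberately larger than the small
#' epidemiological effects reported in consortium meta-analyses so that a
#' cohort of a few thousand subjects per group has the statistical power the
#' downstream recovery checks need; see the methods vignette for the power
#' reasoning behind each default.
#'
#' @param n_per_group Subjects per group (4 groups). Must be >= 2.
#' @param phenotype_spec Tibble (`phenotype`, `tissue`) naming the regional
#'   measures; see [default_phenotype_spec()].
#' @param effect_vector Tibble (`phenotype`, `effect`) of signed standardized
#'   case-control effects (deficits negative); see [default_effect_vector()].
#' @param severity_means Length-4 numeric, strictly increasing, on the 0-4
#'   symptom scale: mean severity for control, subclinical, single, recurrent.
#' @param severity_sd Gaussian jitter SD around the group severity mean;
#'   realized severities are truncated to `[0, 4]`.
#' @param deficit_scale Multiplier mapping a subject's severity to the
#'   phenotype shift along the effect vector. `0` disables the planted effect.
#' @param age_range Length-2 numeric, years; ages drawn uniformly.
#' @param covariate_betas Tibble (`phenotype`, `age_slope`, `sex_offset`,
#'   `icv_slope`) of per-phenotype covariate effects. A single-row tibble
#'   without a `phenotype` column is recycled to every phenotype.
#' @param noise_sd Residual phenotype SD (must be > 0). Phenotypes are
#'   generated on an arbitrary unit scale in which this is the noise SD.
#' @param cognitive_spec Tibble (`test`, `coupling`, `noise_sd`): coupling of
#'   each cognitive score to latent vulnerability (score decreases by
#'   `coupling` per unit vulnerability) and per-test noise SD. Default couples
#'   3 of the 9 tests (matrix, reaction_time, fluid_intelligence).
#' @param seed Integer seed; identical configs give bit-identical cohorts.
#' @return A list of class `cohort_config`.
#' @export
#' @examples
#' cfg <- cohort_config(n_per_group = 50, seed = 1)
#' cfg$severity_means
cohort_config <- function(n_per_group = 2000L,
                          phenotype_spec = default_phenotype_spec(),
                          effect_vector = default_effect_vector(phenotype_spec),
                          severity_means = c(0.5, 1.5, 2.2, 3.0),
                          severity_sd = 0.5,
                          deficit_scale = 1.0,
                          age_range = c(45, 80),
                          covariate_betas = tibble(age_slope = -0.02,
                                                   sex_offset = 0.25,
                                                   icv_slope = 0.5),
                          noise_sd = 1.0,
                          cognitive_spec = default_cognitive_spec(),
                          seed = 20260101L) {
  cfg <- list(
    n_per_group = as.integer(n_per_group),
    phenotype_spec = as_tibble(phenotype_spec),
    effect_vector = as_tibble(effect_vector),
    severity_means = as.numeric(severity_means),
    severity_sd = as.numeric(severity_sd),
    deficit_scale = as.numeric(deficit_scale),
    age_range = as.numeric(age_range),
    covariate_betas = as_tibble(covariate_betas),
    noise_sd = as.numeric(noise_sd),
    cognitive_spec = as_tibble(cognitive_spec),
    seed = as.integer(seed)
  )
  class(cfg) <- "cohort_config"
  validate_cohort_config(cfg)
}

#' Default cognitive coupling specification
#'
#' Three of the nine tests (matrix, reaction_time, fluid_intelligence) are
#' coupled to latent vulnerability, mirroring the pattern of significant
#' case-control cognitive deficits the index is meant to recover; the other
#' six are pure noise.
#'
#' @param affected Character vector of coupled tests.
#' @param coupling Score decrease per unit latent vulnerability for coupled
#'   tests.
#' @param noise_sd Per-test residual SD.
#' @return Tibble (`test`, `coupling`, `noise_sd`).
#' @export
default_cognitive_spec <- function(affected = c("matrix", "reaction_time",
                                                "fluid_intelligence"),
                                   coupling = 0.6, noise_sd = 1.0) {
  tests <- cognitive_tests()
  stopifnot(all(affected %in% tests))
  tibble(test = tests,
         coupling = ifelse(tests %in% affected, coupling, 0),
         noise_sd = noise_sd)
}

validate_cohort_config <- function(cfg) {
  if (cfg$n_per_group < 2L) {
    abort("`n_per_group` must be at least 2.", class = "brainvuln_config_error")
  }
  if (!is.finite(cfg$noise_sd) || cfg$noise_sd <= 0) {
    abort("`noise_sd` must be positive.", class = "brainvuln_config_error")
  }
  if (length(cfg$severity_means) != 4L || any(diff(cfg$severity_means) <= 0)) {
    abort("`severity_means` must be 4 strictly increasing values (control < subclinical < single < recurrent).",
          class = "brainvuln_config_error")
  }
  if (cfg$severity_sd < 0) {
    abort("`severity_sd` must be non-negative.", class = "brainvuln_config_error")
  }
  if (length(cfg$age_range) != 2L || diff(cfg$age_range) <= 0) {
    abort("`age_range` must be (min, max) with min < max.",
          class = "brainvuln_config_error")
  }
  check_tissue_map(cfg$phenotype_spec)
  if (length(unique(cfg$phenotype_spec$tissue)) != 3L) {
    abort("`phenotype_spec` must contain all three tissue classes.",
          class = "brainvuln_config_error")
  }
  if (!all(c("phenotype", "effect") %in% names(cfg$effect_vector)) ||
      !all(cfg$effect_vector$phenotype %in% cfg$phenotype_spec$phenotype)) {
    abort("`effect_vector` must name a subset of `phenotype_spec` phenotypes.",
          class = "brainvuln_config_error")
  }
  if (!all(cfg$cognitive_spec$noise_sd > 0)) {
    abort("cognitive `noise_sd` must be positive.",
          class = "brainvuln_config_error")
  }
  cfg
}

group_levels <- function() c("control", "subclinical", "single", "recurrent")

#' Simulate a synthetic cohort
#'
#' Generates the five linked tables the vulnerability analyses consume:
#' regional phenotypes, covariates (age, sex, ICV), group labels with a
#' continuous 0-4 severity score, cognitive test scores, and the latent truth.
#'
#' The generative model, per subject s and phenotype i:
#' \deqn{y_{si} = b_i + age_s \beta^{age}_i + sex_s \beta^{sex}_i +
#'       icv_s \beta^{icv}_i + v_s E_i + \epsilon_{si}}
#' where the latent vulnerability \eqn{v_s = deficit\_scale \times severity_s},
#' severity is the group mean plus Gaussian jitter truncated to \eqn{[0,4]},
#' \eqn{E} is the signed effect vector and
#' \eqn{\epsilon \sim N(0, noise\_sd^2)}. Cognitive score t is
#' \eqn{-coupling_t v_s + N(0, noise\_sd_t^2)}: cognition degrades with the
#' subject's realized deficit alignment, not with the group label, so controls
#' also carry a cognition-vulnerability association.
#'
#' The caller's RNG state is left untouched; the same config (including seed)
#' reproduces the cohort bit-identically.
#'
#' @param config A [cohort_config()].
#' @return A list of class `synthetic_cohort` with tibbles `phenotypes`
#'   (attr `tissue_map`), `covariates`, `labels`, `cognition`, `truth`, and
#'   the `config`.
#' @export
#' @examples
#' cohort <- simulate_cohort(cohort_config(n_per_group = 20, seed = 7))
#' dplyr::count(cohort$labels, group)
simulate_cohort <- function(config) {
  if (!inherits(config, "cohort_config")) config <- do.call(cohort_config, config)
  validate_cohort_config(config)

  old_seed <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit({
    if (is.null(old_seed)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(config$seed)

  n_g <- config$n_per_group
  groups <- factor(rep(group_levels(), each = n_g), levels = group_levels())
  n <- length(groups)
  subject_id <- sprintf("S%05d", seq_len(n))

  age <- runif(n, config$age_range[1], config$age_range[2])
  sex <- rbinom(n, 1L, 0.5)
  icv <- rlnorm(n, meanlog = log(1.5), sdlog = 0.08) # ~litres
  severity <- config$severity_means[as.integer(groups)] +
    rnorm(n, 0, config$severity_sd)
  severity <- pmin(pmax(severity, 0), 4)
  vulnerability <- config$deficit_scale * severity

  spec <- config$phenotype_spec
  p <- nrow(spec)
  betas <- config$covariate_betas
  if (!"phenotype" %in% names(betas)) {
    betas <- bind_cols(tibble(phenotype = spec$phenotype),
                       betas[rep(1L, p), , drop = FALSE])
  }
  betas <- left_join(spec["phenotype"], betas, by = "phenotype")
  if (anyNA(betas$age_slope)) {
    abort("`covariate_betas` missing rows for some phenotypes.",
          class = "brainvuln_config_error")
  }
  eff <- setNames(rep(0, p), spec$phenotype)
  eff[config$effect_vector$phenotype] <- config$effect_vector$effect
  baseline <- c(thickness = 2.5, fa = 0.45, subcortical_volume = 4.0)[spec$tissue]

  noise <- matrix(rnorm(n * p, 0, config$noise_sd), n, p)
  values <- matrix(baseline, n, p, byrow = TRUE) +
    outer(age, betas$age_slope) + outer(as.numeric(sex), betas$sex_offset) +
    outer(icv, betas$icv_slope) + outer(vulnerability, eff) + noise
  colnames(values) <- spec$phenotype

  cog_spec <- config$cognitive_spec
  cog_noise <- matrix(rnorm(n * nrow(cog_spec)), n, nrow(cog_spec))
  cog <- outer(vulnerability, -cog_spec$coupling) +
    sweep(cog_noise, 2, cog_spec$noise_sd, `*`)
  colnames(cog) <- cog_spec$test

  phenotypes <- bind_cols(tibble(subject_id = subject_id), as_tibble(values))
  attr(phenotypes, "tissue_map") <- spec

  out <- list(
    phenotypes = phenotypes,
    covariates = tibble(subject_id = subject_id, age = age, sex = sex,
                        icv = icv),
    labels = tibble(subject_id = subject_id, group = groups,
                    severity = severity),
    cognition = bind_cols(tibble(subject_id = subject_id), as_tibble(cog)),
    truth = tibble(subject_id = subject_id, vulnerability = vulnerability),
    config = config
  )
  class(out) <- "synthetic_cohort"
  out
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat("<synthetic_cohort> ", nrow(x$covariates), " subjects, ",
      ncol(x$phenotypes) - 1L, " phenotypes, seed ", x$config$seed, "\n",
      sep = "")
  print(dplyr::count(x$labels, .data$group))
  invisible(x)
}

#' @export
print.cohort_config <- function(x, ...) {
  cat("<cohort_config> n_per_group=", x$n_per_group,
      ", phenotypes=", nrow(x$phenotype_spec),
      ", deficit_scale=", x$deficit_scale,
      ", seed=", x$seed, "\n", sep = "")
  invisible(x)
}

# cohort I/O ----------------------------------------------------------------

# TSV writer that preserves doubles exactly across a write/read round trip
# (%.17g is the shortest representation guaranteed to reparse bit-identically),
# so resumed pipeline stages see the very numbers the producing stage saw.
write_tsv_exact <- function(df, path, append = FALSE) {
  out <- df
  for (nm in names(out)) {
    if (is.double(out[[nm]])) out[[nm]] <- sprintf("%.17g", out[[nm]])
  }
  for (nm in names(out)) {
    if (is.character(out[[nm]])) out[[nm]][out[[nm]] == "NA"] <- NA_character_
  }
  suppressMessages(readr::write_tsv(out, path, append = append,
                                    col_names = TRUE))
  invisible(path)
}

# Matching reader: base R's strtod-backed parser recovers %.17g doubles
# bit-identically (readr's fast parser can be one ulp off).
read_tsv_exact <- function(path) {
  df <- utils::read.delim(path, sep = "\t", header = TRUE,
                          comment.char = "#", check.names = FALSE,
                          stringsAsFactors = FALSE)
  as_tibble(df)
}

#' Write / read a cohort as tab-separated tables
#'
#' Writes the five cohort tables as TSV files with a provenance comment line
#' (`# brainvuln seed=<seed> config=<hash>`) above the header, plus a
#' `manifest.json` recording the seed and config hash.
#'
#' @param cohort A `synthetic_cohort`.
#' @param dir Output directory (created if needed).
#' @return `write_cohort()` returns the manifest invisibly; `read_cohort()`
#'   returns a list of tibbles (`phenotypes` carries the `tissue_map` attr).
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  cfg_hash <- digest::digest(cohort$config)
  hdr <- sprintf("# brainvuln seed=%d config=%s", cohort$config$seed, cfg_hash)
  tabs <- c("phenotypes", "covariates", "labels", "cognition", "truth")
  for (nm in tabs) {
    path <- file.path(dir, paste0(nm, ".tsv"))
    writeLines(hdr, path)
    write_tsv_exact(cohort[[nm]], path, append = TRUE)
  }
  readr::write_tsv(attr(cohort$phenotypes, "tissue_map"),
                   file.path(dir, "tissue_map.tsv"))
  manifest <- list(seed = cohort$config$seed, config_hash = cfg_hash,
                   tables = paste0(tabs, ".tsv"),
                   n_subjects = nrow(cohort$covariates))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(dir) {
  rd <- function(nm) read_tsv_exact(file.path(dir, paste0(nm, ".tsv")))
  out <- list(phenotypes = rd("phenotypes"), covariates = rd("covariates"),
              labels = rd("labels"), cognition = rd("cognition"))
  truth_path <- file.path(dir, "truth.tsv")
  if (file.exists(truth_path)) out$truth <- rd("truth")
  tm_path <- file.path(dir, "tissue_map.tsv")
  if (file.exists(tm_path)) {
    attr(out$phenotypes, "tissue_map") <-
      readr::read_tsv(tm_path, show_col_types = FALSE, progress = FALSE)
  }
  out$labels$group <- factor(out$labels$group, levels = group_levels())
  out
}
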