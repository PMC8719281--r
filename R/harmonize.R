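#' Residualize regional phenotypes on nuisance covariates
#'
#' Per phenotype, fits ordinary least squares of the phenotype on an intercept
#' plus the requested covariates over the reference sample, and returns
#' observed minus fitted for *all* subjects. Missing phenotype entries stay
#' missing; no imputation is done anywhere.
#'
#' @param phenotypes Tibble with `subject_id` and one numeric column per
#'   regional phenotype.
#' @param covariates Tibble with `subject_id` and the covariate columns
#'   (typically `age`, `sex`, `icv`). Every subject in `phenotypes` must be
#'   present with non-missing values for the requested covariates.
#' @param covariate_set Non-empty character vector of covariate columns to
#'   regress out.
#' @param reference_ids Optional subject ids on which the regression
#'   coefficients are estimated (e.g. controls only); default uses everyone.
#' @return Tibble of residuals, same shape as `phenotypes`.
#' @export
#' @examples
#' ph <- tibble::tibble(subject_id = c("a", "b", "c", "d"),
#'                      thk = c(1, 2, 3, 4))
#' cv <- tibble::tibble(subject_id = c("a", "b", "c", "d"),
#'                      age = c(50, 60, 70, 80), sex = c(0, 1, 0, 1))
#' residualize(ph, cv, covariate_set = "age")
residualize <- function(phenotypes, covariates,
                        covariate_set = c("age", "sex", "icv"),
                        reference_ids = NULL) {
  if (length(covariate_set) == 0L) {
    abort("`covariate_set` must not be empty.",
          class = "brainvuln_config_error")
  }
  miss_cov <- setdiff(covariate_set, names(covariates))
  if (length(miss_cov)) {
    abort(paste0("Covariate column(s) not found: ",
                 paste(miss_cov, collapse = ", ")),
          class = "brainvuln_config_error")
  }
  unmatched <- setdiff(phenotypes$subject_id, covariates$subject_id)
  if (length(unmatched)) {
    abort(paste0(length(unmatched),
                 " subject(s) in `phenotypes` absent from `covariates`, e.g. ",
                 unmatched[1]),
          class = "brainvuln_alignment_error")
  }
  cov <- covariates[match(phenotypes$subject_id, covariates$subject_id), ,
                    drop = FALSE]
  Xc <- as.matrix(cov[, covariate_set, drop = FALSE])
  if (anyNA(Xc)) {
    abort("Missing covariate values for subjects with phenotype data.",
          class = "brainvuln_alignment_error")
  }
  for (v in covariate_set) {
    if (var(Xc[, v]) == 0) {
      abort(paste0("Degenerate covariate design: `", v, "` is constant."),
            class = "brainvuln_design_error")
    }
  }
  X <- cbind(`(Intercept)` = 1, Xc)
  ref <- if (is.null(reference_ids)) rep(TRUE, nrow(phenotypes))
         else phenotypes$subject_id %in% reference_ids
  if (!any(ref)) {
    abort("No reference subjects found in `phenotypes`.",
          class = "brainvuln_alignment_error")
  }
  if (qr(X[ref, , drop = FALSE])$rank < ncol(X)) {
    abort("Degenerate covariate design: covariates are collinear over the reference sample.",
          class = "brainvuln_design_error")
  }

  pheno_cols <- setdiff(names(phenotypes), "subject_id")
  out <- phenotypes
  for (col in pheno_cols) {
    y <- phenotypes[[col]]
    use <- ref & !is.na(y)
    if (sum(use) <= ncol(X)) {
      abort(paste0("Too few non-missing reference observations for `", col, "`."),
            class = "brainvuln_data_error")
    }
    beta <- lm.fit(X[use, , drop = FALSE], y[use])$coefficients
    out[[col]] <- y - drop(X %*% beta)
  }
  attr(out, "covariate_set") <- covariate_set
  attr(out, "tissue_map") <- attr(phenotypes, "tissue_map")
  out
}

#' Rank-based inverse-normal (Blom) transformation
#'
#' Maps a numeric vector to approximate standard-normal scores through its
#' ranks: a value with (average, for ties) rank r among n non-missing entries
#' becomes \eqn{\Phi^{-1}((r - c)/(n - 2c + 1))} with the Blom constant
#' c = 3/8. Missing values stay missing; the map is strictly increasing over
#' untied values.
#'
#' @param values Numeric vector, possibly with `NA`s; at least 2 non-missing.
#' @param offset Rank offset constant c (default Blom, 3/8).
#' @return Numeric vector of the same length.
#' @export
#' @examples
#' inverse_normal_transform(c(10, 20, 30))
inverse_normal_transform <- function(values, offset = 3 / 8) {
  n <- sum(!is.na(values))
  if (n < 2L) {
    abort("Need at least 2 non-missing values for the inverse-normal transform.",
          class = "brainvuln_data_error")
  }
  nonmiss <- values[!is.na(values)]
  if (all(nonmiss == nonmiss[1])) {
    warn("All values identical; inverse-normal transform returns zeros.")
    out <- values
    out[!is.na(out)] <- 0
    return(out)
  }
  r <- rank(values, na.last = "keep", ties.method = "average")
  qnorm((r - offset) / (n - 2 * offset + 1))
}

#' Harmonize phenotypes into the Z-deviation matrix
#'
#' Composition of [residualize()] and per-column
#' [inverse_normal_transform()]: each subject's row of Z-values measures how
#' far their covariate-adjusted regional anatomy deviates from the reference
#' sample, on a standard-normal scale. These are the P vectors the dot-product
#' index consumes.
#'
#' With `reference = "controls"`, regression coefficients are estimated on
#' controls only and applied to everyone, and the normal scores are anchored
#' in the control distribution: controls get Blom scores from control-only
#' ranks, and non-controls are mapped through the control empirical
#' distribution by linear interpolation (clamped at the control extremes).
#'
#' @inheritParams residualize
#' @param reference `"all"` (default) or `"controls"`.
#' @param labels Tibble (`subject_id`, `group`) — required when
#'   `reference = "controls"`; the control group anchors the reference.
#' @param blom_offset Rank offset constant for the transform.
#' @param icv_volumes_only If `TRUE`, the `icv` covariate is regressed from
#'   volume phenotypes only (requires a tissue map); default regresses ICV
#'   from every phenotype class.
#' @param tissue_map Optional tibble (`phenotype`, `tissue`); defaults to the
#'   `tissue_map` attribute of `phenotypes`.
#' @return Tibble (`subject_id` + one Z column per phenotype) with attributes
#'   `tissue_map`, `covariate_set`, `reference`, `blom_offset`.
#' @export
harmonize <- function(phenotypes, covariates,
                      covariate_set = c("age", "sex", "icv"),
                      reference = c("all", "controls"), labels = NULL,
                      blom_offset = 3 / 8, icv_volumes_only = FALSE,
                      tissue_map = attr(phenotypes, "tissue_map")) {
  reference <- match.arg(reference)
  reference_ids <- NULL
  if (reference == "controls") {
    if (is.null(labels)) {
      abort("`labels` is required when `reference = \"controls\"`.",
            class = "brainvuln_config_error")
    }
    reference_ids <- labels$subject_id[labels$group == "control"]
    if (length(reference_ids) == 0L) {
      abort("No control subjects in `labels`.",
            class = "brainvuln_alignment_error")
    }
  }

  if (icv_volumes_only && "icv" %in% covariate_set) {
    check_tissue_map(tissue_map, setdiff(names(phenotypes), "subject_id"))
    vol <- tissue_map$phenotype[tissue_map$tissue == "subcortical_volume"]
    nonvol <- setdiff(setdiff(names(phenotypes), "subject_id"), vol)
    res_vol <- residualize(phenotypes[c("subject_id", intersect(vol, names(phenotypes)))],
                           covariates, covariate_set, reference_ids)
    res_non <- residualize(phenotypes[c("subject_id", nonvol)], covariates,
                           setdiff(covariate_set, "icv"), reference_ids)
    res <- left_join(res_non, res_vol, by = "subject_id")
    res <- res[c("subject_id", setdiff(names(phenotypes), "subject_id"))]
  } else {
    res <- residualize(phenotypes, covariates, covariate_set, reference_ids)
  }

  is_ref <- if (is.null(reference_ids)) rep(TRUE, nrow(res))
            else res$subject_id %in% reference_ids
  z <- res
  for (col in setdiff(names(res), "subject_id")) {
    z[[col]] <- reference_normal_scores(res[[col]], is_ref, blom_offset)
  }
  attr(z, "tissue_map") <- tissue_map
  attr(z, "covariate_set") <- covariate_set
  attr(z, "reference") <- reference
  attr(z, "blom_offset") <- blom_offset
  z
}

# Normal scores anchored in the reference subsample: reference entries get
# Blom scores from reference-only ranks; the rest are interpolated through the
# reference empirical distribution (clamped at its extremes).
reference_normal_scores <- function(x, is_ref, offset) {
  if (all(is_ref)) return(inverse_normal_transform(x, offset))
  out <- rep(NA_real_, length(x))
  ref_x <- x[is_ref]
  z_ref <- inverse_normal_transform(ref_x, offset)
  out[is_ref] <- z_ref
  ok <- !is.na(ref_x)
  ord <- order(ref_x[ok])
  xs <- ref_x[ok][ord]
  zs <- z_ref[!is.na(ref_x)][ord]
  keep <- !duplicated(xs)
  todo <- !is_ref & !is.na(x)
  if (any(todo)) {
    out[todo] <- stats::approx(xs[keep], zs[keep], xout = x[todo],
                               rule = 2, ties = "ordered")$y
  }
  out
}

#' Write a Z matrix with its provenance sidecar
#'
#' @param z A Z matrix from [harmonize()].
#' @param path Output TSV path; a `<path>.json` sidecar records the covariate
#'   set, reference mode and Blom constant.
#' @return `path`, invisibly.
#' @export
write_zmatrix <- function(z, path) {
  write_tsv_exact(z, path)
  jsonlite::write_json(
    list(covariate_set = attr(z, "covariate_set"),
         reference = attr(z, "reference"),
         blom_offset = attr(z, "blom_offset")),
    paste0(path, ".json"), auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}
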