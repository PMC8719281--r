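#' Meta-analytic dot-product vulnerability index
#'
#' Per subject, the normalized dot product between the subject's Z-deviation
#' vector P and a signed meta-analytic case-control effect-size vector E:
#' \deqn{DP = \frac{1}{N}\sum_{i=1}^{N} P_i E_i}
#' over the subject's non-missing phenotypes shared with the effect vector
#' (N is that per-subject count, so the scale stays comparable across
#' subjects with missing regions). Deviation in the deficit direction (P and
#' E of the same sign) increases the index.
#'
#' @param z Z matrix from [harmonize()] (`subject_id` + phenotype columns).
#' @param effects Tibble (`phenotype`, `effect`): signed effects, deficits
#'   negative; phenotype names must intersect the Z columns and contain at
#'   least one nonzero effect.
#' @return Tibble (`subject_id`, `edp`, `n_phenotypes`). Subjects with no
#'   non-missing shared phenotype get `NA` with a warning.
#' @export
#' @examples
#' z <- tibble::tibble(subject_id = "s1", a = 1, b = -1, c = 2)
#' compute_edp(z, tibble::tibble(phenotype = c("a", "b", "c"),
#'                               effect = c(0.5, -0.5, 0.25)))
compute_edp <- function(z, effects) {
  if (!all(c("phenotype", "effect") %in% names(effects))) {
    abort("`effects` must have columns `phenotype` and `effect`.",
          class = "brainvuln_config_error")
  }
  shared <- intersect(effects$phenotype, setdiff(names(z), "subject_id"))
  if (length(shared) == 0L) {
    abort("No phenotype shared between the Z matrix and the effect vector.",
          class = "brainvuln_alignment_error")
  }
  e <- effects$effect[match(shared, effects$phenotype)]
  if (all(e == 0)) {
    abort("Effect vector has no nonzero entry among shared phenotypes.",
          class = "brainvuln_config_error")
  }
  P <- as.matrix(z[, shared, drop = FALSE])
  prod <- sweep(P, 2, e, `*`)
  n_avail <- rowSums(!is.na(P))
  edp <- rowSums(prod, na.rm = TRUE) / n_avail
  edp[n_avail == 0L] <- NA_real_
  if (any(n_avail == 0L)) {
    warn(paste0(sum(n_avail == 0L),
                " subject(s) had no non-missing shared phenotype; edp set to NA."))
  }
  tibble(subject_id = z$subject_id, edp = edp,
         n_phenotypes = as.integer(n_avail))
}

#' Whole-brain comparison biomarkers
#'
#' Per subject and tissue class, the mean of the non-missing Z values:
#' whole-brain average gray-matter thickness, subcortical volume and FA
#' deviations, the conventional global measures the dot-product index is
#' compared against.
#'
#' @param z Z matrix from [harmonize()].
#' @param tissue_map Tibble (`phenotype`, `tissue`) covering every Z column;
#'   defaults to the matrix's `tissue_map` attribute.
#' @return Tibble (`subject_id`, `mean_thickness_z`, `mean_subcort_z`,
#'   `mean_fa_z`).
#' @export
whole_brain_means <- function(z, tissue_map = attr(z, "tissue_map")) {
  if (is.null(tissue_map)) {
    abort("`tissue_map` is required (none attached to `z`).",
          class = "brainvuln_config_error")
  }
  cols <- setdiff(names(z), "subject_id")
  check_tissue_map(tissue_map, cols)
  out <- tibble(subject_id = z$subject_id)
  nm <- c(thickness = "mean_thickness_z", subcortical_volume = "mean_subcort_z",
          fa = "mean_fa_z")
  for (tis in c("thickness", "subcortical_volume", "fa")) {
    members <- intersect(tissue_map$phenotype[tissue_map$tissue == tis], cols)
    if (length(members) == 0L) {
      abort(paste0("Tissue class `", tis, "` has no phenotypes in the Z matrix."),
            class = "brainvuln_config_error")
    }
    out[[nm[[tis]]]] <- rowMeans(as.matrix(z[, members, drop = FALSE]),
                                 na.rm = TRUE)
  }
  out[["mean_thickness_z"]][is.nan(out[["mean_thickness_z"]])] <- NA_real_
  out[["mean_subcort_z"]][is.nan(out[["mean_subcort_z"]])] <- NA_real_
  out[["mean_fa_z"]][is.nan(out[["mean_fa_z"]])] <- NA_real_
  out
}
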