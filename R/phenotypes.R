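#' Default regional phenotype specification
#'
#' The standard set of 64 bilateral-averaged structural phenotypes used by the
#' vulnerability indices: 33 Desikan-Killiany cortical gray-matter thickness
#' regions, 24 white-matter tract fractional-anisotropy (FA) values, and 7
#' subcortical gray-matter volumes. Lateral-ventricle volume is deliberately
#' excluded by default (it is not part of the three-tissue index set); pass a
#' custom spec to include it.
#'
#' @param n_thickness,n_fa,n_subcortical Optional counts to truncate (or, if
#'   larger than the named sets, extend with numbered placeholders) each tissue
#'   class. Defaults use the full named sets.
#' @return A tibble with columns `phenotype` and `tissue`
#'   (`thickness`, `fa`, or `subcortical_volume`).
#' @export
#' @examples
#' default_phenotype_spec()
default_phenotype_spec <- function(n_thickness = 33L, n_fa = 24L,
                                   n_subcortical = 7L) {
  make_set <- function(names, n, prefix) {
    if (n <= length(names)) names[seq_len(n)]
    else c(names, paste0(prefix, seq_len(n - length(names))))
  }
  thickness <- make_set(dk_thickness_regions, n_thickness, "thickness_extra")
  fa <- make_set(fa_tracts, n_fa, "fa_extra")
  subcort <- make_set(subcortical_structures, n_subcortical, "subcort_extra")
  tibble(
    phenotype = c(paste0("thk_", thickness), paste0("fa_", fa),
                  paste0("vol_", subcort)),
    tissue = rep(c("thickness", "fa", "subcortical_volume"),
                 c(length(thickness), length(fa), length(subcort)))
  )
}

# 33 Desikan-Killiany cortical regions (temporal pole omitted), bilateral mean
dk_thickness_regions <- c(
  "bankssts", "caudalanteriorcingulate", "caudalmiddlefrontal", "cuneus",
  "entorhinal", "frontalpole", "fusiform", "inferiorparietal",
  "inferiortemporal", "insula", "isthmuscingulate", "lateraloccipital",
  "lateralorbitofrontal", "lingual", "medialorbitofrontal", "middletemporal",
  "paracentral", "parahippocampal", "parsopercularis", "parsorbitalis",
  "parstriangularis", "pericalcarine", "postcentral", "posteriorcingulate",
  "precentral", "precuneus", "rostralanteriorcingulate",
  "rostralmiddlefrontal", "superiorfrontal", "superiorparietal",
  "superiortemporal", "supramarginal", "transversetemporal"
)

# 24 white-matter tracts (bilateral mean where applicable), skeletonized FA
fa_tracts <- c(
  "ACR", "ALIC", "BCC", "CC", "CGC", "CGH", "CR", "CST", "EC", "FX", "FXST",
  "GCC", "IC", "IFO", "PCR", "PLIC", "PTR", "RLIC", "SCC", "SCR", "SFO",
  "SLF", "SS", "UNC"
)

# 7 subcortical gray-matter structures, bilateral mean volumes
subcortical_structures <- c(
  "thalamus", "caudate", "putamen", "pallidum", "hippocampus", "amygdala",
  "accumbens"
)

#' The nine cognitive tests in the battery
#'
#' Touchscreen-style cognitive battery covered by the cognition analyses:
#' Matrix reasoning, Reaction Time, Numeric Memory, Pairs Matching, Trail
#' Making 1 and 2, Symbol Digit substitution, Tower rearranging, and Fluid
#' Intelligence. Scores are oriented so that higher = better performance.
#'
#' @return Character vector of length 9.
#' @export
cognitive_tests <- function() {
  c("matrix", "reaction_time", "numeric_memory", "pairs_match", "trails_1",
    "trails_2", "symbol_digit", "tower", "fluid_intelligence")
}

#' Default planted case-control effect-size vector
#'
#' A signed standardized effect per phenotype (case minus control; structural
#' deficits negative) used by the synthetic cohort generator and as the
#' reference vector in the worked examples. The pattern is deterministic and
#' chosen to mirror the qualitative structure reported for depression:
#' FA effects uniformly negative (white matter tracks symptom burden),
#' cortical thickness effects mixed-sign with a near-zero mean (so the
#' whole-brain mean thickness is nearly uninformative even though individual
#' regions carry signal), and small mixed subcortical volume effects.
#' Real consortium-published effect sizes are not bundled; supply them as a
#' two-column table (`phenotype`, `effect`) for analyses of real data.
#'
#' @param phenotype_spec A phenotype spec tibble, see [default_phenotype_spec()].
#' @return A tibble with columns `phenotype` and `effect`.
#' @export
#' @examples
#' head(default_effect_vector())
default_effect_vector <- function(phenotype_spec = default_phenotype_spec()) {
  stopifnot(all(c("phenotype", "tissue") %in% names(phenotype_spec)))
  eff <- function(n, from, to) if (n == 1L) (from + to) / 2 else seq(from, to, length.out = n)
  by_tissue <- split(phenotype_spec$phenotype, phenotype_spec$tissue)
  out <- phenotype_spec
  out$effect <- NA_real_
  ranges <- list(thickness = c(-0.28, 0.20), fa = c(-0.30, -0.08),
                 subcortical_volume = c(-0.12, 0.04))
  for (tis in names(by_tissue)) {
    idx <- out$tissue == tis
    r <- ranges[[tis]] %||% c(-0.1, 0.1)
    out$effect[idx] <- eff(sum(idx), r[1], r[2])
  }
  select(out, "phenotype", "effect")
}

# tissue_map accessors ------------------------------------------------------

check_tissue_map <- function(tissue_map, phenotypes = NULL) {
  if (!all(c("phenotype", "tissue") %in% names(tissue_map))) {
    abort("`tissue_map` must have columns `phenotype` and `tissue`.")
  }
  if (anyDuplicated(tissue_map$phenotype)) {
    abort("`tissue_map` assigns some phenotype more than one tissue class.")
  }
  bad <- setdiff(unique(tissue_map$tissue),
                 c("thickness", "fa", "subcortical_volume"))
  if (length(bad)) {
    abort(paste0("Unknown tissue class(es): ", paste(bad, collapse = ", ")))
  }
  if (!is.null(phenotypes)) {
    missing <- setdiff(phenotypes, tissue_map$phenotype)
    if (length(missing)) {
      abort(paste0("Phenotypes missing from `tissue_map`: ",
                   paste(head(missing, 5), collapse = ", "),
                   if (length(missing) > 5) ", ..."))
    }
  }
  invisible(tissue_map)
}
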