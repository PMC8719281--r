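# Residualize a numeric vector on covariates (default age + sex) over the
# non-missing sample, then optionally z-scale. Constant input -> zeros with a
# warning (degenerate biomarker).
adjust_and_scale <- function(x, covariates, covariate_set = c("age", "sex"),
                             scale = TRUE, label = "biomarker") {
  ok <- !is.na(x) & stats::complete.cases(covariates[, covariate_set,
                                                     drop = FALSE])
  out <- rep(NA_real_, length(x))
  if (sum(ok) < length(covariate_set) + 2L) {
    abort(paste0("Too few observations to adjust `", label, "`."),
          class = "brainvuln_data_error")
  }
  if (var(x[ok]) == 0) {
    warn(paste0("`", label, "` is constant; adjusted values set to 0."))
    out[ok] <- 0
    return(out)
  }
  X <- cbind(1, as.matrix(covariates[ok, covariate_set, drop = FALSE]))
  res <- lm.fit(X, x[ok])$residuals
  if (scale) {
    s <- sd(res)
    res <- if (s == 0) rep(0, length(res)) else (res - mean(res)) / s
  }
  out[ok] <- res
  out
}

align_tables <- function(scores, covariates, labels = NULL) {
  out <- inner_join(scores, covariates, by = "subject_id")
  if (!is.null(labels)) out <- inner_join(out, labels, by = "subject_id")
  if (nrow(out) < nrow(scores)) {
    abort("Some subjects in `scores` are missing covariates or labels.",
          class = "brainvuln_alignment_error")
  }
  out
}

#' Group-mean biomarker profiles
#'
#' For each severity group, the mean and standard error of each biomarker
#' after residualizing it on age and sex over the whole cohort and z-scaling,
#' together with the group's mean symptom severity — the group-level profile
#' the severity correlation is computed from.
#'
#' @param scores Tibble (`subject_id` + biomarker columns), e.g. the combined
#'   output of [compute_edp()], [whole_brain_means()] and [compute_qri()].
#' @param covariates Tibble (`subject_id`, `age`, `sex`).
#' @param labels Tibble (`subject_id`, `group`, `severity`); every subject
#'   must be labeled, each group needs n >= 2.
#' @param biomarkers Biomarker columns to summarize; default all non-id
#'   numeric columns of `scores`.
#' @return Tibble of class `group_summary`, long format: `group`, `n`,
#'   `mean_severity`, `biomarker`, `mean`, `se`.
#' @export
group_profile <- function(scores, covariates, labels,
                          biomarkers = setdiff(names(scores),
                                               c("subject_id", "n_phenotypes"))) {
  dat <- align_tables(scores, covariates, labels)
  counts <- table(factor(dat$group, levels = group_levels()))
  if (any(counts < 2L)) {
    abort(paste0("Group(s) with fewer than 2 subjects: ",
                 paste(names(counts)[counts < 2L], collapse = ", ")),
          class = "brainvuln_analysis_error")
  }
  adj <- purrr::map(setNames(biomarkers, biomarkers),
                    ~ adjust_and_scale(dat[[.x]], dat, label = .x))
  rows <- purrr::imap(adj, function(v, bm) {
    dat |>
      mutate(.v = v) |>
      group_by(.data$group) |>
      summarise(n = sum(!is.na(.data$.v)),
                mean_severity = mean(.data$severity, na.rm = TRUE),
                mean = mean(.data$.v, na.rm = TRUE),
                se = sd(.data$.v, na.rm = TRUE) /
                  sqrt(sum(!is.na(.data$.v))),
                .groups = "drop") |>
      mutate(biomarker = bm, .after = "mean_severity")
  })
  out <- bind_rows(rows)
  class(out) <- c("group_summary", class(out))
  out
}

#' Correlation of group-mean biomarker with group-mean severity
#'
#' Pearson correlation of the four (mean severity, mean biomarker) points of
#' a [group_profile()]. With only four groups this correlation has 2 degrees
#' of freedom; it is reported descriptively (`r`, `r_squared`) with the
#' small-sample basis annotated, and no p-value is attached.
#'
#' @param summary A `group_summary` from [group_profile()].
#' @param biomarker Biomarker name to extract.
#' @return One-row tibble: `biomarker`, `r`, `r_squared`, `n_groups`, `df`,
#'   `note`.
#' @export
groupmean_correlation <- function(summary, biomarker) {
  s <- summary[summary$biomarker == biomarker, ]
  if (nrow(s) != 4L || anyNA(s$mean) || anyNA(s$mean_severity)) {
    abort(paste0("Need the 4 group means for `", biomarker, "`."),
          class = "brainvuln_analysis_error")
  }
  if (var(s$mean) == 0 || var(s$mean_severity) == 0) {
    abort("Undefined correlation: zero variance across group means.",
          class = "brainvuln_analysis_error")
  }
  r <- cor(s$mean_severity, s$mean)
  tibble(biomarker = biomarker, r = r, r_squared = r^2, n_groups = 4L,
         df = 2L, note = "descriptive 4-point correlation (df=2)")
}

#' Individual-level symptom-severity association
#'
#' Pearson correlation between an age/sex-corrected biomarker and the
#' continuous symptom-severity score over individual subjects, with the exact
#' t-statistic \eqn{t = r\sqrt{n-2}/\sqrt{1-r^2}} and two-sided p-value from
#' the t distribution with n-2 df. By default the three depression groups are
#' pooled and controls are excluded.
#'
#' @inheritParams group_profile
#' @param biomarker Biomarker column in `scores`.
#' @param subset `"depressed"` (subclinical + single + recurrent pooled,
#'   default) or `"all"`.
#' @return One-row tibble of class `symptom_association`: `biomarker`,
#'   `subset`, `r`, `t`, `p`, `n`.
#' @export
symptom_association <- function(scores, covariates, labels, biomarker,
                                subset = c("depressed", "all")) {
  subset <- match.arg(subset)
  dat <- align_tables(scores, covariates, labels)
  dat$.adj <- adjust_and_scale(dat[[biomarker]], dat, label = biomarker)
  if (subset == "depressed") {
    dat <- filter(dat, .data$group %in% c("subclinical", "single", "recurrent"))
  }
  ok <- !is.na(dat$.adj) & !is.na(dat$severity)
  n <- sum(ok)
  if (n < 4L) {
    abort("Fewer than 4 subjects available for the symptom association.",
          class = "brainvuln_data_error")
  }
  r <- cor(dat$.adj[ok], dat$severity[ok])
  out <- tibble(biomarker = biomarker, subset = subset, r = r,
                t = r_to_t(r, n), p = r_to_p(r, n), n = n)
  class(out) <- c("symptom_association", class(out))
  out
}

r_to_t <- function(r, n) {
  if (abs(r) >= 1) return(sign(r) * Inf)
  r * sqrt(n - 2) / sqrt(1 - r^2)
}

r_to_p <- function(r, n) {
  t <- r_to_t(r, n)
  if (!is.finite(t)) return(.Machine$double.xmin)
  2 * pt(-abs(t), df = n - 2)
}
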