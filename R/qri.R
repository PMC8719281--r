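#' Fit a linear quantile regression of a phenotype on age
#'
#' Estimates the age-conditional tau-quantile line
#' \eqn{Q_\tau(y \mid age) = a + b \cdot age} by minimizing the check loss
#' \eqn{\sum_i \rho_\tau(y_i - a - b\,age_i)},
#' \eqn{\rho_\tau(u) = u(\tau - 1\{u<0\})}. Fitting is delegated to
#' `quantreg::rq.fit.br` (exact simplex solution at a data vertex); for
#' continuous data the minimizing vertex is almost surely unique.
#'
#' @param y Numeric phenotype values.
#' @param age Numeric ages (same length); must not be constant.
#' @param tau Quantile level in (0, 1).
#' @return A list of class `quantile_fit`: `tau`, `intercept`, `slope`, `n`,
#'   `check_loss`.
#' @export
#' @examples
#' set.seed(1)
#' age <- runif(50, 45, 80)
#' fit_quantile_regression(2 + 0.5 * age + rnorm(50), age, 0.5)
fit_quantile_regression <- function(y, age, tau) {
  stopifnot(length(y) == length(age))
  ok <- !is.na(y) & !is.na(age)
  y <- y[ok]; age <- age[ok]
  if (length(y) < 10L) {
    abort("Need at least 10 paired non-missing (y, age) observations.",
          class = "brainvuln_data_error")
  }
  if (!(tau > 0 && tau < 1)) {
    abort("`tau` must be strictly between 0 and 1.",
          class = "brainvuln_config_error")
  }
  if (var(age) == 0) {
    abort("Degenerate design: `age` is constant.",
          class = "brainvuln_design_error")
  }
  if (var(y) == 0) {
    cf <- c(y[1], 0) # exact: zero loss, unique since age varies
  } else {
    X <- cbind(1, age)
    cf <- withCallingHandlers(
      quantreg::rq.fit.br(X, y, tau = tau)$coefficients,
      warning = function(w) {
        if (grepl("nonunique", conditionMessage(w))) {
          invokeRestart("muffleWarning")
        }
      })
  }
  structure(list(tau = tau, intercept = unname(cf[1]), slope = unname(cf[2]),
                 n = length(y),
                 check_loss = check_loss(y - cf[1] - cf[2] * age, tau)),
            class = "quantile_fit")
}

check_loss <- function(u, tau) sum(u * (tau - (u < 0)))

#' @export
print.quantile_fit <- function(x, ...) {
  cat(sprintf("<quantile_fit> tau=%.2f  intercept=%.4g  slope=%.4g  n=%d\n",
              x$tau, x$intercept, x$slope, x$n))
  invisible(x)
}

#' Fit the normative quantile lines for every phenotype
#'
#' Fits, on the whole sample (the normative reference), three quantile
#' regressions of each phenotype on age — at the 5th, 50th and 95th
#' percentiles by default. Optionally stratified by sex (separate fits per
#' stratum, applied to matching subjects downstream).
#'
#' @param phenotypes Tibble (`subject_id` + phenotype columns).
#' @param covariates Tibble with `subject_id`, `age` (and `sex` when
#'   stratifying).
#' @param taus Quantile levels (default `c(0.05, 0.5, 0.95)`).
#' @param by_sex If `TRUE`, fit within sex strata.
#' @return Tibble of class `qri_fits`: `phenotype`, (`sex`,) `tau`,
#'   `intercept`, `slope`, `n`.
#' @export
fit_quantile_models <- function(phenotypes, covariates,
                                taus = c(0.05, 0.5, 0.95), by_sex = FALSE) {
  cov <- covariates[match(phenotypes$subject_id, covariates$subject_id), ,
                    drop = FALSE]
  if (anyNA(cov$age)) {
    abort("Missing `age` for subjects with phenotype data.",
          class = "brainvuln_alignment_error")
  }
  cols <- setdiff(names(phenotypes), "subject_id")
  strata <- if (by_sex) split(seq_len(nrow(cov)), cov$sex)
            else list(`1` = seq_len(nrow(cov)))
  rows <- list()
  for (s in names(strata)) {
    idx <- strata[[s]]
    for (col in cols) {
      for (tau in taus) {
        f <- fit_quantile_regression(phenotypes[[col]][idx], cov$age[idx], tau)
        row <- tibble(phenotype = col, tau = tau, intercept = f$intercept,
                      slope = f$slope, n = f$n)
        if (by_sex) row <- bind_cols(tibble(sex = as.numeric(s)), row)
        rows[[length(rows) + 1L]] <- row
      }
    }
  }
  out <- bind_rows(rows)
  class(out) <- c("qri_fits", class(out))
  out
}

#' @export
tidy.qri_fits <- function(x, ...) {
  as_tibble(unclass(x))
}

#' @export
glance.qri_fits <- function(x, ...) {
  tibble(n_phenotypes = length(unique(x$phenotype)),
         taus = paste(sort(unique(x$tau)), collapse = "/"),
         by_sex = "sex" %in% names(x))
}

#' Score one observation against fitted quantile lines
#'
#' Regional aging score at the subject's age: `+1` if the observed value lies
#' strictly below the fitted 5th-percentile line (tissue more atrophied than
#' expected for that age — older-looking), `-1` if strictly above the fitted
#' 95th-percentile line (younger-looking), else `0`. Boundary equality gives
#' `0` (strict inequalities).
#'
#' @param value Observed phenotype value.
#' @param fit05,fit95 `quantile_fit` objects at tau 0.05 and 0.95.
#' @param age Subject age.
#' @return Integer score in \{-1, 0, +1\}.
#' @export
score_region <- function(value, fit05, fit95, age) {
  p05 <- fit05$intercept + fit05$slope * age
  p95 <- fit95$intercept + fit95$slope * age
  if (p05 > p95) {
    warn(sprintf("Crossed quantile lines at age %.2f (5th=%.4g > 95th=%.4g).",
                 age, p05, p95))
  }
  if (is.na(value)) return(NA_integer_)
  if (value < p05) 1L else if (value > p95) -1L else 0L
}

#' Score every subject-region against the normative quantile lines
#'
#' Vectorized application of the strict-inequality scoring rule of
#' [score_region()] to the whole cohort. Ages at which a phenotype's fitted
#' 5th-percentile line exceeds its 95th-percentile line (quantile crossing)
#' are scored by the same rules and logged in the `crossings` attribute.
#'
#' @param phenotypes Tibble (`subject_id` + phenotype columns).
#' @param covariates Tibble with `subject_id`, `age` (and `sex` for
#'   sex-stratified fits).
#' @param fits A `qri_fits` table containing taus 0.05 and 0.95.
#' @return Tibble (`subject_id` + one integer score column per phenotype),
#'   with attribute `crossings` (tibble `phenotype`, `subject_id`, `age`).
#' @export
score_regions <- function(phenotypes, covariates, fits) {
  cov <- covariates[match(phenotypes$subject_id, covariates$subject_id), ,
                    drop = FALSE]
  by_sex <- "sex" %in% names(fits)
  cols <- setdiff(names(phenotypes), "subject_id")
  out <- tibble(subject_id = phenotypes$subject_id)
  crossings <- list()
  get_line <- function(col, tau, sex_val) {
    sel <- fits$phenotype == col & fits$tau == tau
    if (by_sex) sel <- sel & fits$sex == sex_val
    if (sum(sel) != 1L) {
      abort(paste0("Expected exactly one tau=", tau, " fit for `", col, "`."),
            class = "brainvuln_config_error")
    }
    fits[sel, ]
  }
  sex_vals <- if (by_sex) sort(unique(cov$sex)) else 0
  for (col in cols) {
    score <- rep(NA_integer_, nrow(out))
    for (sv in sex_vals) {
      rows <- if (by_sex) which(cov$sex == sv) else seq_len(nrow(out))
      f05 <- get_line(col, 0.05, sv)
      f95 <- get_line(col, 0.95, sv)
      age <- cov$age[rows]
      p05 <- f05$intercept + f05$slope * age
      p95 <- f95$intercept + f95$slope * age
      crossed <- p05 > p95
      if (any(crossed)) {
        crossings[[length(crossings) + 1L]] <-
          tibble(phenotype = col, subject_id = out$subject_id[rows][crossed],
                 age = age[crossed])
      }
      v <- phenotypes[[col]][rows]
      s <- ifelse(v < p05, 1L, ifelse(v > p95, -1L, 0L))
      score[rows] <- as.integer(s)
    }
    out[[col]] <- score
  }
  crossings <- if (length(crossings)) bind_rows(crossings)
               else tibble(phenotype = character(), subject_id = character(),
                           age = numeric())
  if (nrow(crossings)) {
    warn(sprintf("Quantile crossing at %d subject-region combinations (see attr 'crossings').",
                 nrow(crossings)))
  }
  attr(out, "crossings") <- crossings
  out
}

#' Aggregate regional aging scores into tissue and whole-brain indices
#'
#' Tissue-specific indices are the per-subject means of the regional -1/0/+1
#' scores over each tissue class; the whole-brain index is the unweighted
#' mean of the three tissue indices. All lie in `[-1, 1]`; positive values
#' indicate anatomy older-looking than expected for the subject's age.
#'
#' @param region_scores Tibble from [score_regions()].
#' @param tissue_map Tibble (`phenotype`, `tissue`) covering every scored
#'   region; defaults to the `tissue_map` attribute.
#' @return Tibble (`subject_id`, `qri_thickness`, `qri_subcort`, `qri_fa`,
#'   `qri_whole`).
#' @export
aggregate_qri <- function(region_scores,
                          tissue_map = attr(region_scores, "tissue_map")) {
  if (is.null(tissue_map)) {
    abort("`tissue_map` is required.", class = "brainvuln_config_error")
  }
  cols <- setdiff(names(region_scores), "subject_id")
  check_tissue_map(tissue_map, cols)
  out <- tibble(subject_id = region_scores$subject_id)
  nm <- c(thickness = "qri_thickness", subcortical_volume = "qri_subcort",
          fa = "qri_fa")
  empty_tissue <- FALSE
  for (tis in names(nm)) {
    members <- intersect(tissue_map$phenotype[tissue_map$tissue == tis], cols)
    if (length(members) == 0L) {
      warn(paste0("No scored regions for tissue `", tis,
                  "`; its index (and the whole-brain index) is missing."))
      out[[nm[[tis]]]] <- NA_real_
      empty_tissue <- TRUE
    } else {
      m <- rowMeans(as.matrix(region_scores[, members, drop = FALSE]),
                    na.rm = TRUE)
      m[is.nan(m)] <- NA_real_
      out[[nm[[tis]]]] <- m
    }
  }
  out$qri_whole <- (out$qri_thickness + out$qri_subcort + out$qri_fa) / 3
  out
}

#' Quantile regression index, end to end
#'
#' Fits the normative 5th/50th/95th quantile lines on the whole sample,
#' scores every subject-region, and aggregates to tissue and whole-brain
#' indices.
#'
#' @inheritParams fit_quantile_models
#' @param tissue_map Tibble (`phenotype`, `tissue`); defaults to the
#'   phenotype table's attribute.
#' @return List of class `qri_result`: `scores` (subject-level indices),
#'   `region_scores`, `fits`, `crossings`.
#' @export
compute_qri <- function(phenotypes, covariates,
                        tissue_map = attr(phenotypes, "tissue_map"),
                        taus = c(0.05, 0.5, 0.95), by_sex = FALSE) {
  fits <- fit_quantile_models(phenotypes, covariates, taus = taus,
                              by_sex = by_sex)
  region_scores <- score_regions(phenotypes, covariates, fits)
  scores <- aggregate_qri(region_scores, tissue_map)
  structure(list(scores = scores, region_scores = region_scores, fits = fits,
                 crossings = attr(region_scores, "crossings")),
            class = "qri_result")
}

#' @export
print.qri_result <- function(x, ...) {
  cat("<qri_result> ", nrow(x$scores), " subjects, ",
      length(unique(x$fits$phenotype)), " regions, ",
      nrow(x$crossings), " quantile crossings\n", sep = "")
  print(head(x$scores))
  invisible(x)
}

#' @export
tidy.qri_result <- function(x, ...) x$scores

#' @export
glance.qri_result <- function(x, ...) {
  tibble(n_subjects = nrow(x$scores),
         n_regions = length(unique(x$fits$phenotype)),
         n_crossings = nrow(x$crossings),
         mean_qri_whole = mean(x$scores$qri_whole, na.rm = TRUE))
}
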