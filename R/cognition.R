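new_association_profile <- function(df, name) {
  attr(df, "profile") <- name
  class(df) <- c("association_profile", class(df))
  df
}

#' @export
print.association_profile <- function(x, ...) {
  cat("<association_profile> ", attr(x, "profile"), "\n", sep = "")
  NextMethod()
}

#' Cognitive deficit profile: case groups versus controls
#'
#' Per cognitive test, the pooled-variance two-sample t-statistic comparing
#' the pooled depression groups against controls, after correcting each test
#' score for age and sex over the whole cohort. With
#' `deficit_positive = TRUE` (default) the t is signed so that worse
#' performance in the case groups is positive (scores are oriented
#' higher = better).
#'
#' @param cognition Tibble (`subject_id` + one column per test).
#' @param covariates Tibble (`subject_id`, `age`, `sex`).
#' @param labels Tibble (`subject_id`, `group`).
#' @param mdd_groups Which groups form the case pool (default all three
#'   depression groups, mirroring the whole-group-vs-control contrast).
#' @param deficit_positive Sign convention flag.
#' @param name Profile label.
#' @return Tibble of class `association_profile`: `test`, `t`, `estimate`
#'   (Cohen's d for the contrast), `p`, `n`.
#' @export
cognitive_deficit_profile <- function(cognition, covariates, labels,
                                      mdd_groups = c("subclinical", "single",
                                                     "recurrent"),
                                      deficit_positive = TRUE,
                                      name = "mdd_vs_control") {
  dat <- align_tables(cognition, covariates, labels)
  is_case <- dat$group %in% mdd_groups
  is_ctrl <- dat$group == "control"
  if (!any(is_case) || !any(is_ctrl)) {
    abort("Both the case pool and the control group must be non-empty.",
          class = "brainvuln_analysis_error")
  }
  tests <- setdiff(names(cognition), "subject_id")
  rows <- purrr::map(tests, function(ts) {
    x <- adjust_and_scale(dat[[ts]], dat, scale = FALSE, label = ts)
    a <- x[is_ctrl & !is.na(x)]
    b <- x[is_case & !is.na(x)]
    if (length(a) < 10L || length(b) < 10L) {
      abort(paste0("Fewer than 10 subjects per group for test `", ts, "`."),
            class = "brainvuln_data_error")
    }
    if (var(a) == 0 && var(b) == 0) {
      warn(paste0("Test `", ts, "` is constant; t undefined."))
      return(tibble(test = ts, t = NA_real_, estimate = NA_real_,
                    p = NA_real_, n = length(a) + length(b)))
    }
    n1 <- length(a); n2 <- length(b)
    sp2 <- ((n1 - 1) * var(a) + (n2 - 1) * var(b)) / (n1 + n2 - 2)
    diff <- mean(a) - mean(b) # control minus case: positive = case deficit
    if (!deficit_positive) diff <- -diff
    t <- diff / sqrt(sp2 * (1 / n1 + 1 / n2))
    tibble(test = ts, t = t, estimate = diff / sqrt(sp2),
           p = 2 * pt(-abs(t), df = n1 + n2 - 2), n = n1 + n2)
  })
  new_association_profile(bind_rows(rows), name)
}

#' Biomarker-cognition association profile
#'
#' Per cognitive test, the simple linear model of the age/sex-corrected test
#' score on the age/sex-corrected biomarker within the chosen subset
#' (controls or the pooled depression groups), reporting the slope
#' t-statistic (identical to the correlation t for a simple regression), the
#' correlation, the two-sided p, and n. With `deficit_positive = TRUE`
#' (default) t and r are flipped so that a biomarker association with *worse*
#' cognition is positive, putting the profile on the same scale as the
#' case-control deficit profile.
#'
#' @param scores Tibble (`subject_id` + biomarker columns).
#' @param cognition Tibble (`subject_id` + test columns).
#' @param covariates Tibble (`subject_id`, `age`, `sex`).
#' @param labels Tibble (`subject_id`, `group`).
#' @param biomarker Biomarker column name.
#' @param subset `"controls"` or `"depressed"` (pooled case groups).
#' @param deficit_positive Sign convention flag.
#' @param name Profile label; default derived from biomarker and subset.
#' @return Tibble of class `association_profile`: `test`, `t`, `estimate`
#'   (signed correlation), `p`, `n`.
#' @export
biomarker_cognition_profile <- function(scores, cognition, covariates, labels,
                                        biomarker,
                                        subset = c("controls", "depressed"),
                                        deficit_positive = TRUE,
                                        name = NULL) {
  subset <- match.arg(subset)
  name <- name %||% paste0(biomarker, "_in_", subset)
  dat <- align_tables(scores, covariates, labels)
  dat <- inner_join(dat, cognition, by = "subject_id")
  keep <- if (subset == "controls") dat$group == "control"
          else dat$group %in% c("subclinical", "single", "recurrent")
  dat <- dat[keep, , drop = FALSE]
  if (nrow(dat) < 10L) {
    abort("Fewer than 10 subjects in the requested subset.",
          class = "brainvuln_data_error")
  }
  if (all(is.na(dat[[biomarker]])) ||
      var(dat[[biomarker]], na.rm = TRUE) == 0) {
    abort(paste0("`", biomarker, "` is constant; association undefined."),
          class = "brainvuln_analysis_error")
  }
  bm <- adjust_and_scale(dat[[biomarker]], dat, label = biomarker)
  tests <- setdiff(names(cognition), "subject_id")
  rows <- purrr::map(tests, function(ts) {
    y <- adjust_and_scale(dat[[ts]], dat, scale = FALSE, label = ts)
    ok <- !is.na(bm) & !is.na(y)
    n <- sum(ok)
    if (n < 4L || var(y[ok]) == 0) {
      warn(paste0("Test `", ts, "` degenerate in subset; t undefined."))
      return(tibble(test = ts, t = NA_real_, estimate = NA_real_,
                    p = NA_real_, n = n))
    }
    r <- cor(bm[ok], y[ok])
    # higher biomarker with lower score = deficit-direction association
    if (deficit_positive) r <- -r
    r <- min(max(r, -1), 1)
    tibble(test = ts, t = r_to_t(r, n), estimate = r, p = r_to_p(r, n), n = n)
  })
  new_association_profile(bind_rows(rows), name)
}

#' Compare two association profiles
#'
#' Pattern similarity between two per-test t-score profiles: the Pearson
#' correlation of the two t vectors (with its small-sample df annotated), the
#' mean and SD of |t| per profile, and a two-sided paired t-test across tests
#' comparing the |t| magnitudes of the two profiles. Tests with an undefined
#' t in either profile are dropped pairwise.
#'
#' @param a,b `association_profile` tibbles over the same test list.
#' @param compare_on `"abs"` (default; the paired comparison uses |t|) or
#'   `"signed"`.
#' @return One-row tibble of class `profile_comparison`.
#' @export
compare_profiles <- function(a, b, compare_on = c("abs", "signed")) {
  compare_on <- match.arg(compare_on)
  if (!identical(a$test, b$test)) {
    abort("Profiles have different test lists; align them first.",
          class = "brainvuln_alignment_error")
  }
  ok <- !is.na(a$t) & !is.na(b$t)
  if (sum(ok) < 3L) {
    abort("Fewer than 3 tests with defined t in both profiles.",
          class = "brainvuln_data_error")
  }
  ta <- a$t[ok]; tb <- b$t[ok]
  n <- length(ta)
  pattern_r <- cor(ta, tb)
  va <- if (compare_on == "abs") abs(ta) else ta
  vb <- if (compare_on == "abs") abs(tb) else tb
  d <- va - vb
  note <- NA_character_
  if (var(d) == 0) {
    paired_t <- if (all(d == 0)) 0 else NA_real_
    paired_p <- if (all(d == 0)) 1 else NA_real_
    note <- "zero-variance paired differences"
  } else {
    tt <- t.test(va, vb, paired = TRUE)
    paired_t <- unname(tt$statistic)
    paired_p <- tt$p.value
  }
  out <- tibble(
    profile_a = attr(a, "profile") %||% "a",
    profile_b = attr(b, "profile") %||% "b",
    n_tests = n,
    pattern_r = pattern_r,
    pattern_p = r_to_p(pattern_r, n),
    df = n - 2L,
    mean_abs_t_a = mean(abs(ta)), sd_abs_t_a = sd(abs(ta)),
    mean_abs_t_b = mean(abs(tb)), sd_abs_t_b = sd(abs(tb)),
    paired_t = paired_t, paired_p = paired_p,
    note = note
  )
  class(out) <- c("profile_comparison", class(out))
  out
}

#' @export
glance.profile_comparison <- function(x, ...) {
  select(as_tibble(unclass(x)), "profile_a", "profile_b", "pattern_r",
         "pattern_p", "paired_p")
}

#' @export
tidy.association_profile <- function(x, ...) {
  mutate(as_tibble(unclass(x)), profile = attr(x, "profile") %||% NA_character_,
         .before = 1)
}
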