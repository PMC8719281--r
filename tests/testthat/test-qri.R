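qf <- function(tau, intercept, slope) {
  structure(list(tau = tau, intercept = intercept, slope = slope),
            class = "quantile_fit")
}

test_that("quantile fits handle noise-free and constant data exactly", {
  age <- c(45, 48, 52, 55, 59, 63, 66, 70, 74, 78, 80, 81)
  for (tau in c(0.05, 0.5, 0.95)) {
    f <- fit_quantile_regression(2 + 0.5 * age, age, tau)
    expect_equal(f$intercept, 2, tolerance = 1e-8)
    expect_equal(f$slope, 0.5, tolerance = 1e-8)
    fc <- fit_quantile_regression(rep(3, 12), age, tau)
    expect_equal(fc$intercept, 3)
    expect_equal(fc$slope, 0)
    expect_equal(fc$check_loss, 0)
  }
})

test_that("quantile fit preconditions are enforced", {
  age <- runif(12, 45, 80)
  y <- rnorm(12)
  expect_error(fit_quantile_regression(y, rep(60, 12), 0.5),
               class = "brainvuln_design_error")
  expect_error(fit_quantile_regression(y[1:5], age[1:5], 0.5),
               class = "brainvuln_data_error")
  expect_error(fit_quantile_regression(y, age, 0),
               class = "brainvuln_config_error")
  expect_error(fit_quantile_regression(y, age, 1),
               class = "brainvuln_config_error")
})

test_that("fitted lines match exhaustive two-point vertex enumeration", {
  set.seed(31)
  for (rep in 1:6) {
    age <- runif(12, 45, 80)
    y <- 3 - 0.02 * age + rnorm(12, 0, 0.4)
    for (tau in c(0.05, 0.5, 0.95)) {
      f <- fit_quantile_regression(y, age, tau)
      o <- oracle_rq_vertex(y, age, tau)
      expect_equal(f$check_loss, unname(o["loss"]), tolerance = 1e-8)
      expect_equal(f$intercept, unname(o["intercept"]), tolerance = 1e-6)
      expect_equal(f$slope, unname(o["slope"]), tolerance = 1e-6)
    }
  }
})

test_that("fitted loss never exceeds the best constant model's loss", {
  set.seed(32)
  age <- runif(40, 45, 80)
  y <- 2 + 0.03 * age + rexp(40)
  for (tau in c(0.05, 0.5, 0.95)) {
    f <- fit_quantile_regression(y, age, tau)
    const_loss <- min(vapply(y, function(c0)
      oracle_check_loss(y - c0, tau), numeric(1)))
    expect_lte(f$check_loss, const_loss + 1e-10)
  }
})

test_that("in-sample coverage honors the quantile subgradient condition", {
  set.seed(33)
  age <- runif(2000, 45, 80)
  y <- 3 - 0.02 * age + rnorm(2000, 0, 0.5)
  for (tau in c(0.05, 0.5, 0.95)) {
    f <- fit_quantile_regression(y, age, tau)
    below <- mean(y < f$intercept + f$slope * age)
    expect_lt(abs(below - tau), 0.02)
  }
})

test_that("regional scoring follows the strict-inequality percentile rule", {
  f05 <- qf(0.05, 1, 0.01)
  f95 <- qf(0.95, 3, 0.01)
  age <- 60
  p05 <- 1 + 0.01 * 60 # 1.6
  expect_identical(score_region(p05, f05, f95, age), 0L) # boundary -> 0
  expect_identical(score_region(p05 - 1e-9, f05, f95, age), 1L)
  expect_identical(score_region(3 + 0.6 + 1e-9, f05, f95, age), -1L)
  expect_identical(score_region(2, f05, f95, age), 0L)
  expect_identical(score_region(NA, f05, f95, age), NA_integer_)
  # crossed lines: scored by the same rules, with a warning
  expect_warning(s <- score_region(2, qf(0.05, 10, 0), qf(0.95, 0, 0), 60),
                 "Crossed")
  expect_identical(s, 1L)
})

test_that("vectorized scoring agrees with the scalar rule and logs crossings", {
  set.seed(34)
  n <- 200
  age <- runif(n, 45, 80)
  ph <- tibble::tibble(subject_id = sprintf("s%03d", 1:n),
                       r1 = 2 - 0.01 * age + rnorm(n, 0, 0.3),
                       r2 = 5 - 0.02 * age + rnorm(n, 0, 0.5))
  cov <- tibble::tibble(subject_id = ph$subject_id, age = age)
  fits <- fit_quantile_models(ph, cov)
  sc <- score_regions(ph, cov, fits)
  for (col in c("r1", "r2")) {
    f05 <- fits[fits$phenotype == col & fits$tau == 0.05, ]
    f95 <- fits[fits$phenotype == col & fits$tau == 0.95, ]
    manual <- vapply(seq_len(n), function(i) {
      score_region(ph[[col]][i], qf(0.05, f05$intercept, f05$slope),
                   qf(0.95, f95$intercept, f95$slope), age[i])
    }, integer(1))
    expect_identical(sc[[col]], manual)
  }
  expect_identical(nrow(attr(sc, "crossings")), 0L)

  # force a crossing: swap the 5th and 95th percentile lines of r1
  xfits <- fits
  i05 <- which(xfits$phenotype == "r1" & xfits$tau == 0.05)
  i95 <- which(xfits$phenotype == "r1" & xfits$tau == 0.95)
  xfits[c(i05, i95), c("intercept", "slope")] <-
    xfits[c(i95, i05), c("intercept", "slope")]
  expect_warning(scx <- score_regions(ph, cov, xfits), "crossing")
  expect_identical(sort(unique(attr(scx, "crossings")$phenotype)), "r1")
})

test_that("aggregation matches a brute-force group-by mean", {
  set.seed(35)
  p <- 30
  tm <- tibble::tibble(phenotype = paste0("r", 1:p),
                       tissue = sample(c("thickness", "fa",
                                         "subcortical_volume"), p,
                                       replace = TRUE))
  m <- matrix(sample(c(-1L, 0L, 1L), 50 * p, replace = TRUE), 50, p,
              dimnames = list(NULL, tm$phenotype))
  scores <- dplyr::bind_cols(tibble::tibble(subject_id = sprintf("s%02d", 1:50)),
                             tibble::as_tibble(m))
  q <- aggregate_qri(scores, tm)
  for (i in c(1, 17, 50)) {
    for (tis in unique(tm$tissue)) {
      cols <- tm$phenotype[tm$tissue == tis]
      expected <- sum(m[i, cols]) / length(cols)
      got <- switch(tis, thickness = q$qri_thickness[i],
                    fa = q$qri_fa[i], subcortical_volume = q$qri_subcort[i])
      expect_equal(got, expected, tolerance = 1e-12)
    }
    expect_equal(q$qri_whole[i],
                 mean(c(q$qri_thickness[i], q$qri_subcort[i], q$qri_fa[i])),
                 tolerance = 1e-15)
  }
  expect_true(all(abs(q$qri_whole) <= 1))
})

test_that("aggregation handles degenerate score patterns", {
  tm <- tibble::tibble(phenotype = c("t1", "t2", "v1", "f1"),
                       tissue = c("thickness", "thickness",
                                  "subcortical_volume", "fa"))
  sc <- tibble::tibble(subject_id = "s1", t1 = 0L, t2 = 0L, v1 = 0L, f1 = 0L)
  q <- aggregate_qri(sc, tm)
  expect_true(all(as.matrix(q[-1]) == 0))

  sc2 <- tibble::tibble(subject_id = "s1", t1 = 1L, t2 = 1L, v1 = 0L,
                        f1 = -1L)
  q2 <- aggregate_qri(sc2, tm)
  expect_equal(unlist(q2[c("qri_thickness", "qri_subcort", "qri_fa",
                           "qri_whole")], use.names = FALSE),
               c(1, 0, -1, 0))

  # tissue with no scored region: its index and the whole-brain one go missing
  expect_warning(q3 <- aggregate_qri(sc2[c("subject_id", "t1", "t2", "v1")],
                                     tm[1:3, ]),
                 "fa")
  expect_true(is.na(q3$qri_fa) && is.na(q3$qri_whole))
})

test_that("negating values and reflecting fits swaps +1 and -1 scores", {
  set.seed(36)
  n <- 300
  age <- runif(n, 45, 80)
  ph <- tibble::tibble(subject_id = sprintf("s%03d", 1:n),
                       r1 = 2 - 0.01 * age + rnorm(n, 0, 0.3))
  cov <- tibble::tibble(subject_id = ph$subject_id, age = age)
  fits <- fit_quantile_models(ph, cov)
  sc <- score_regions(ph, cov, fits)
  neg <- ph; neg$r1 <- -neg$r1
  rfits <- fits
  rfits$intercept <- -rfits$intercept
  rfits$slope <- -rfits$slope
  rfits$tau <- round(1 - rfits$tau, 10) # reflected 5th line becomes the 95th
  nsc <- score_regions(neg, cov, rfits)
  expect_identical(nsc$r1, -sc$r1)
})

test_that("null simulation scores ~5% of regions at each tail", {
  set.seed(37)
  n <- 2000; p <- 20
  age <- runif(n, 45, 80)
  vals <- matrix(2.5 - 0.01 * age + rnorm(n * p, 0, 0.5), n, p)
  colnames(vals) <- paste0("r", 1:p)
  ph <- dplyr::bind_cols(tibble::tibble(subject_id = sprintf("s%04d", 1:n)),
                         tibble::as_tibble(vals))
  cov <- tibble::tibble(subject_id = ph$subject_id, age = age)
  sc <- score_regions(ph, cov, fit_quantile_models(ph, cov))
  m <- as.matrix(sc[-1])
  expect_lt(abs(mean(m == 1L) - 0.05), 0.01)
  expect_lt(abs(mean(m == -1L) - 0.05), 0.01)
})

test_that("sex-stratified fits score subjects against their own stratum", {
  set.seed(38)
  n <- 400
  age <- runif(n, 45, 80)
  sex <- rep(c(0, 1), each = n / 2)
  # strong sex offset: pooled lines would mis-score both strata
  ph <- tibble::tibble(subject_id = sprintf("s%03d", 1:n),
                       r1 = 2 + 3 * sex - 0.01 * age + rnorm(n, 0, 0.2))
  cov <- tibble::tibble(subject_id = ph$subject_id, age = age, sex = sex)
  fits <- fit_quantile_models(ph, cov, by_sex = TRUE)
  expect_setequal(unique(fits$sex), c(0, 1))
  sc <- score_regions(ph, cov, fits)
  expect_lt(abs(mean(sc$r1 == 1L) - 0.05), 0.04)
  expect_lt(abs(mean(sc$r1 == -1L) - 0.05), 0.04)
})
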