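make_cov <- function(n, seed = 1) {
  set.seed(seed)
  tibble::tibble(subject_id = sprintf("s%04d", seq_len(n)),
                 age = runif(n, 45, 80), sex = rbinom(n, 1, 0.5),
                 icv = rlnorm(n, log(1.5), 0.08))
}

test_that("residualize removes an exact linear covariate effect", {
  cov <- make_cov(50)
  ph <- tibble::tibble(subject_id = cov$subject_id,
                       thk = 1.2 + 0.3 * cov$age)
  res <- residualize(ph, cov, covariate_set = "age")
  expect_lt(max(abs(res$thk)), 1e-10)
})

test_that("residualize matches the normal-equations solution", {
  cov <- make_cov(400, seed = 2)
  set.seed(3)
  y <- 2 + 0.1 * cov$age - 0.5 * cov$sex + rnorm(400)
  ph <- tibble::tibble(subject_id = cov$subject_id, p1 = y)
  res <- residualize(ph, cov, covariate_set = c("age", "sex", "icv"))
  X <- cbind(1, cov$age, cov$sex, cov$icv)
  beta <- solve(t(X) %*% X, t(X) %*% y)
  expect_equal(res$p1, drop(y - X %*% beta), tolerance = 1e-10)
})

test_that("residuals of a covariate-free phenotype are a centered copy", {
  cov <- make_cov(5000, seed = 4)
  set.seed(5)
  y <- rnorm(5000)
  res <- residualize(tibble::tibble(subject_id = cov$subject_id, p = y), cov)
  expect_lt(abs(cor(res$p, cov$age)), 0.05)
  expect_gt(cor(res$p, y), 0.999)
})

test_that("degenerate designs and misalignments are rejected", {
  cov <- make_cov(20)
  ph <- tibble::tibble(subject_id = cov$subject_id, p = rnorm(20))
  expect_error(residualize(ph, cov, covariate_set = character(0)),
               class = "brainvuln_config_error")
  cov2 <- cov; cov2$sex <- 1
  expect_error(residualize(ph, cov2), class = "brainvuln_design_error",
               regexp = "sex")
  expect_error(residualize(ph, cov[-1, ]),
               class = "brainvuln_alignment_error")
  expect_error(residualize(ph, dplyr::rename(cov, ICV = icv)),
               class = "brainvuln_config_error")
  # missing phenotype values stay missing, untouched by the fit
  ph$p[3] <- NA
  expect_true(is.na(residualize(ph, cov)$p[3]))
})

test_that("inverse-normal transform reproduces hand-computed Blom scores", {
  z <- inverse_normal_transform(c(10, 20, 30))
  expect_equal(z, c(-0.869424, 0, 0.869424), tolerance = 1e-4)
  # any odd-length strictly increasing vector maps its middle to exactly 0
  z7 <- inverse_normal_transform(c(3, 9, 27, 81, 243, 729, 2187))
  expect_identical(z7[4], 0)
  # tied pair shares the average rank, hence both map to 0 (with the
  # degenerate-input warning, since the whole vector is one tie)
  expect_warning(z2 <- inverse_normal_transform(c(5, 5)), "identical")
  expect_equal(z2, c(0, 0))
})

test_that("inverse-normal transform handles missing and degenerate input", {
  x <- c(4, NA, 1, 7)
  z <- inverse_normal_transform(x)
  expect_true(is.na(z[2]))
  expect_identical(order(z[-2]), order(x[-2]))
  expect_warning(zc <- inverse_normal_transform(c(2, 2, 2)), "identical")
  expect_equal(zc, c(0, 0, 0))
  expect_error(inverse_normal_transform(c(1, NA, NA)),
               class = "brainvuln_data_error")
})

test_that("harmonize matches a 3-subject hand calculation", {
  # ages 50/60/80, phenotype 10/14/12; OLS on age by hand:
  #   mean age = 190/3, mean y = 12
  #   Sxy = (50-190/3)(10-12) + (60-190/3)(14-12) + (80-190/3)(12-12) = 20
  #   Sxx = (50-190/3)^2 + (60-190/3)^2 + (80-190/3)^2 = 1400/3
  #   slope = 20/(1400/3) = 3/70, intercept = 12 - (3/70)(190/3) = 65/7
  # residuals = y - 65/7 - (3/70) age = (-10/7, 15/7, -5/7), ranks (1, 3, 2)
  cov <- tibble::tibble(subject_id = c("a", "b", "c"), age = c(50, 60, 80))
  ph <- tibble::tibble(subject_id = c("a", "b", "c"), p = c(10, 14, 12))
  res <- residualize(ph, cov, covariate_set = "age")
  expect_equal(res$p, c(-10 / 7, 15 / 7, -5 / 7), tolerance = 1e-10)
  expected <- qnorm((c(1, 3, 2) - 3 / 8) / 3.25)
  z <- harmonize(ph, cov, covariate_set = "age")
  expect_equal(z$p, expected, tolerance = 1e-12)
})

test_that("normal scores are invariant to monotone re-scaling of the input", {
  set.seed(7)
  y <- rlnorm(200)
  # ranks unchanged => identical output, for any strictly increasing map
  expect_equal(inverse_normal_transform(y),
               inverse_normal_transform(log(y)), tolerance = 1e-12)
  expect_equal(inverse_normal_transform(y),
               inverse_normal_transform(100 + 3 * y), tolerance = 1e-12)
})

test_that("Z columns are rank-identical to their residuals", {
  cov <- make_cov(200, seed = 6)
  set.seed(7)
  y <- rlnorm(200)
  ph <- tibble::tibble(subject_id = cov$subject_id, p = y)
  z <- harmonize(ph, cov)
  res <- residualize(ph, cov)
  expect_identical(order(z$p), order(res$p))
})

test_that("harmonize removes a planted age slope", {
  cov <- make_cov(5000, seed = 8)
  set.seed(9)
  ph <- tibble::tibble(subject_id = cov$subject_id,
                       p = 3 - 0.04 * cov$age + rnorm(5000, 0, 0.5))
  z <- harmonize(ph, cov)
  expect_lt(abs(cor(z$p, cov$age)), 0.05)
  expect_equal(mean(z$p), 0, tolerance = 4 / sqrt(5000))
  expect_gt(sd(z$p), 0.8)
  expect_lt(sd(z$p), 1.2)
})

test_that("Z columns are near standard normal for continuous input", {
  cov <- make_cov(1000, seed = 10)
  set.seed(11)
  passes <- vapply(1:10, function(i) {
    ph <- tibble::tibble(subject_id = cov$subject_id,
                         p = 2 + 0.02 * cov$age + rexp(1000))
    z <- harmonize(ph, cov)
    suppressWarnings(ks.test(z$p, "pnorm")$p.value) > 0.01
  }, logical(1))
  expect_gte(sum(passes), 9L)
})

test_that("controls-anchored harmonization centers controls, not cases", {
  cov <- make_cov(600, seed = 12)
  labels <- tibble::tibble(subject_id = cov$subject_id,
                           group = rep(c("control", "recurrent"),
                                       each = 300))
  set.seed(13)
  y <- rnorm(600)
  y[301:600] <- y[301:600] - 2 # cases shifted far below controls
  ph <- tibble::tibble(subject_id = cov$subject_id, p = y)
  z <- harmonize(ph, cov, reference = "controls", labels = labels)
  ctrl <- 1:300
  expect_equal(mean(z$p[ctrl]), 0, tolerance = 4 / sqrt(300))
  # cases sit in the left tail of the control distribution
  expect_lt(mean(z$p[-ctrl]), -1)
  # interpolation through the control distribution is monotone in the
  # control-anchored residuals (clamping at the control extremes may create
  # ties, hence non-strict)
  res <- residualize(ph, cov, reference_ids = labels$subject_id[ctrl])
  expect_true(all(diff(z$p[-ctrl][order(res$p[-ctrl])]) >= 0))
  expect_error(harmonize(ph, cov, reference = "controls"),
               class = "brainvuln_config_error")
})

test_that("icv_volumes_only restricts the ICV adjustment to volumes", {
  spec <- default_phenotype_spec(n_thickness = 2, n_fa = 2, n_subcortical = 2)
  cov <- make_cov(800, seed = 14)
  set.seed(15)
  vals <- sapply(seq_len(6), function(i) 1 + 2 * cov$icv + rnorm(800, 0, 0.1))
  colnames(vals) <- spec$phenotype
  ph <- dplyr::bind_cols(tibble::tibble(subject_id = cov$subject_id),
                         tibble::as_tibble(vals))
  z <- harmonize(ph, cov, icv_volumes_only = TRUE, tissue_map = spec)
  thk <- spec$phenotype[spec$tissue == "thickness"][1]
  vol <- spec$phenotype[spec$tissue == "subcortical_volume"][1]
  expect_gt(abs(cor(z[[thk]], cov$icv)), 0.8) # ICV left in non-volumes
  expect_lt(abs(cor(z[[vol]], cov$icv)), 0.1) # ICV removed from volumes
})
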