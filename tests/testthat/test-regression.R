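test_that("fitOLS matches the normal equations and handles degenerate inputs", {
  set.seed(31)
  X <- cbind(`(Intercept)` = 1, x1 = stats::rnorm(20),
             x2 = stats::rnorm(20), x3 = stats::rnorm(20))
  y <- stats::rnorm(20)
  fit <- fitOLS(y, X)
  expect_equal(fit$coefficients, oracleOLS(y, X), tolerance = 1e-8,
               ignore_attr = TRUE)
  lmfit <- summary(stats::lm(y ~ X[, -1]))
  expect_equal(unname(fit$p), unname(lmfit$coefficients[, 4]),
               tolerance = 1e-10)
  expect_equal(fit$pF, unname(stats::pf(lmfit$fstatistic[1],
                                        lmfit$fstatistic[2],
                                        lmfit$fstatistic[3],
                                        lower.tail = FALSE)),
               tolerance = 1e-10)

  # noise-free line
  x <- 1:10
  fit2 <- fitOLS(3 + 2 * x, cbind(1, x))
  expect_equal(unname(fit2$coefficients), c(3, 2), tolerance = 1e-12)
  expect_lt(fit2$rss, 1e-20)

  # constant response: zero slopes, model F p-value 1
  fit3 <- fitOLS(rep(5, 20), X)
  expect_equal(unname(fit3$coefficients[-1]), c(0, 0, 0), tolerance = 1e-12)
  expect_equal(fit3$pF, 1)

  expect_error(fitOLS(y, cbind(X, dup = X[, "x1"])), "collinear.*dup")
})

test_that("backwardSelect recovers noise-free planted models exactly", {
  co <- makeCohort(20, 20, seed = 32)
  sex <- as.numeric(co$sex == "M")
  age <- co$age_years

  m2 <- backwardSelect(1 + 0.5 * sex, co)
  expect_equal(m2$model, "M2")
  expect_equal(m2$fit$coefficients[["sex"]], 0.5, tolerance = 1e-12)

  m3 <- backwardSelect(1 - 0.01 * age, co)
  expect_equal(m3$model, "M3")

  m4 <- backwardSelect(1 + 0.5 * sex - 0.01 * age, co)
  expect_equal(m4$model, "M4")

  m5 <- backwardSelect(1 + 0.5 * sex - 0.01 * age + 0.02 * sex * age, co)
  expect_equal(m5$model, "M5")
  expect_equal(m5$fit$coefficients[["sex:age"]], 0.02, tolerance = 1e-10)

  m1 <- backwardSelect(rep(2, 40), co)
  expect_equal(m1$model, "M1")
})

test_that("backwardSelect agrees with an lm/drop1 stepwise oracle", {
  co <- makeCohort(15, 15, seed = 33)
  set.seed(33)
  for (k in 1:60) {
    y <- stats::rnorm(30) +
      sample(c(0, 0.3, 1), 1) * as.numeric(co$sex == "M") +
      sample(c(0, 0.05), 1) * co$age_years
    expect_equal(backwardSelect(y, co)$model, lmStepwiseOracle(y, co))
  }
})

test_that("single-term partial F equals the squared coefficient t", {
  co <- makeCohort(12, 14, seed = 34)
  designs <- fcnets:::sexAgeDesigns(co)
  set.seed(34)
  for (k in 1:20) {
    y <- stats::rnorm(26)
    full <- fitOLS(y, designs$M5)
    red <- fitOLS(y, designs$M4)
    Fpart <- (red$rss - full$rss) / full$sigma2
    expect_equal(Fpart, unname(full$t[["sex:age"]]^2), tolerance = 1e-8)
    expect_equal(
      stats::pf(Fpart, 1, full$dfResid, lower.tail = FALSE),
      unname(full$p[["sex:age"]]), tolerance = 1e-8)
  }
})

test_that("vectorized mass-univariate selection matches per-edge backwardSelect", {
  co <- makeCohort(25, 25, seed = 35)
  ef <- makeEffectMap(80, 15, 10, 5,
                      effectSizes = c(sex = 0.6, age = 0.06, int = 0.05),
                      noiseSd = 1, seed = 35)
  fce <- simulateDirectZ(co, ef, seed = 35)
  rep <- runMassUnivariate(fce)
  Y <- groupFCMatrix(fce)
  for (e in seq(1, 80, by = 3)) {
    bs <- backwardSelect(Y[, e], co)
    expect_equal(rep$results$model[e], bs$model)
    if (bs$model != "M1") {
      expect_equal(rep$results$p_F[e], bs$fit$pF, tolerance = 1e-10)
    }
    if ("sex" %in% bs$terms) {
      expect_equal(rep$results$beta_sex[e],
                   bs$fit$coefficients[["sex"]], tolerance = 1e-10)
      expect_equal(rep$results$p_sex[e], bs$fit$p[["sex"]],
                   tolerance = 1e-10)
    }
  }
})

test_that("report structure: absent terms carry no p-value; flags match signs", {
  co <- makeCohort(30, 30, seed = 36)
  ef <- makeEffectMap(200, 30, 20, 0, noiseSd = 0.5, seed = 36)
  fce <- simulateDirectZ(co, ef, seed = 36)
  rep <- runMassUnivariate(fce)
  res <- rep$results
  expect_true(all(is.na(res$p_sex[res$model %in% c("M1", "M3")])))
  expect_true(all(is.na(res$p_age[res$model %in% c("M1", "M2")])))
  expect_true(all(is.na(res$p_int[res$model != "M5"])))
  expect_true(all(!is.na(res$p_sex[res$model %in% c("M2", "M4", "M5")])))
  expect_true(all(res$dir_sex[!is.na(res$beta_sex) & res$beta_sex > 0]
                  == "M>F"))
  expect_true(all(res$dir_age[!is.na(res$beta_age) & res$beta_age < 0]
                  == "older<younger"))
  cnt <- rep$counts
  expect_equal(sum(cnt$models), 200)
  expect_equal(cnt$n_significant_models, sum(cnt$models_significant))
})

test_that("Bonferroni threshold is alpha/m with the truncated 1e-6 label", {
  thr <- bonferroniThreshold(0.05, 6670)
  expect_equal(thr$threshold, 0.05 / 6670)
  expect_equal(thr$mantissa, 7.49)
  expect_equal(thr$label, "7.49E-6")
})

test_that("BH-FDR correction is available and less strict than Bonferroni", {
  co <- makeCohort(40, 40, seed = 37)
  ef <- makeEffectMap(120, 25, 0, 0, effectSizes = c(sex = 0.8),
                      noiseSd = 1, seed = 37)
  fce <- simulateDirectZ(co, ef, seed = 37)
  bonf <- runMassUnivariate(fce, correction = "bonferroni")
  fdr <- runMassUnivariate(fce, correction = "bh_fdr")
  expect_gte(sum(fdr$results$sig_model), sum(bonf$results$sig_model))
  expect_identical(bonf$results$model, fdr$results$model)
})

test_that("augmentWithCovariates refits selected models and flags collinearity", {
  co <- makeCohort(25, 25, seed = 38)
  ef <- makeEffectMap(40, 10, 0, 0, effectSizes = c(sex = 1),
                      noiseSd = 0.5, seed = 38)
  fce <- simulateDirectZ(co, ef, seed = 38)
  rep <- runMassUnivariate(fce)

  # covariate orthogonal to the design and the responses: sex p-values move
  # only through the residual d.f.
  X5 <- fcnets:::sexAgeDesigns(co)$M5
  Y <- groupFCMatrix(fce)
  set.seed(38)
  raw <- stats::rnorm(50)
  ortho <- stats::resid(stats::lm(raw ~ cbind(X5[, -1], Y)))
  co2 <- co
  co2$ortho <- as.numeric(ortho)
  fce2 <- FCExperiment(Y, co2, edgeIndex(fce))
  aug <- augmentWithCovariates(rep, fce2, "ortho")
  # with an orthogonal covariate the coefficient and RSS are unchanged, so
  # the sex p-value moves only through the lost residual d.f.:
  # t_new = t_old * sqrt((n - p - 1)/(n - p)), tested per edge exactly
  res <- rep$results
  pmod <- c(M2 = 2, M3 = 2, M4 = 3, M5 = 4)
  for (e in which(!is.na(res$p_sex))) {
    df <- 50 - pmod[[res$model[e]]]
    tOld <- stats::qt(1 - res$p_sex[e] / 2, df)
    pNew <- 2 * stats::pt(abs(tOld) * sqrt((df - 1) / df), df - 1,
                          lower.tail = FALSE)
    expect_equal(aug$results$p_sex[e], pNew, tolerance = 1e-6)
  }
  expect_equal(aug$comparison$sex$lost, 0)

  co3 <- co
  co3$sexdup <- as.numeric(co$sex == "M")
  fce3 <- FCExperiment(Y, co3, edgeIndex(fce))
  expect_error(augmentWithCovariates(rep, fce3, "sexdup"), "collinear")

  co4 <- co
  co4$flat <- 1
  fce4 <- FCExperiment(Y, co4, edgeIndex(fce))
  expect_error(augmentWithCovariates(rep, fce4, "flat"), "zero-variance")
  expect_error(augmentWithCovariates(rep, fce2, "nope"), "not in cohort")
})

test_that("stratifiedAgeSlopes recovers group-specific planted slopes", {
  co <- makeCohort(20, 20, seed = 39)
  sex <- as.numeric(co$sex == "M")
  age <- co$age_years
  # female-only decline, noise-free: z = 1 - 0.02*age for females, 1 for males
  Y <- cbind(e1 = 1 - 0.02 * age * (1 - sex),
             e2 = 0.5 + 0 * age,
             e3 = 1 - 0.01 * age,                      # equal slopes
             e4 = 1 - 0.01 * age - 0.01 * age * (1 - sex)) # f steeper
  fce <- FCExperiment(Y, co)
  out <- stratifiedAgeSlopes(fce)
  expect_equal(out$results$slope_female[1], -0.02, tolerance = 1e-12)
  expect_equal(out$results$slope_male[1], 0, tolerance = 1e-12)
  expect_equal(out$results$slope_male[3], out$results$slope_female[3],
               tolerance = 1e-12)

  expect_equal(out$results$slope_male[4], -0.01, tolerance = 1e-12)
  expect_equal(out$results$slope_female[4], -0.02, tolerance = 1e-12)
  expect_equal(out$counts$both_negative_female_steeper, 1)

  # slopes equal the general OLS path on the group subset
  set.seed(39)
  Yn <- Y + matrix(stats::rnorm(160, sd = 0.1), 40, 4)
  fceN <- FCExperiment(Yn, co)
  outN <- stratifiedAgeSlopes(fceN)
  male <- co$sex == "M"
  fit <- fitOLS(Yn[male, 2], cbind(1, age = age[male]))
  expect_equal(outN$results$slope_male[2], fit$coefficients[["age"]],
               tolerance = 1e-10)
  expect_equal(outN$results$p_male[2], fit$p[["age"]], tolerance = 1e-10)
  expect_true(out$counts$both_negative_female_steeper >= 1)

  expect_error(stratifiedAgeSlopes(FCExperiment(Y[c(1, 2, 39, 40), ],
                                                co[c(1, 2, 39, 40), ])),
               "at least 3")
})

test_that("edgeCognitionCorrelation finds planted associations only", {
  co <- makeCohort(30, 30, seed = 40)
  ef <- makeEffectMap(60, 0, 0, 0, noiseSd = 1, seed = 40)
  fce <- simulateDirectZ(co, ef, seed = 40)
  Y <- groupFCMatrix(fce)
  co$cognition_1 <- Y[, 7] + stats::rnorm(60, sd = 0.01)
  fce <- FCExperiment(Y, co, edgeIndex(fce))
  out <- edgeCognitionCorrelation(fce, "cognition_1")
  expect_true(7 %in% (out$significant$edge_id + 1))
  # shared correlation kernel
  expect_equal(out$results$r[7], stats::cor(co$cognition_1, Y[, 7]),
               tolerance = 1e-12)
  co$flat <- 2
  fceF <- FCExperiment(Y, co, edgeIndex(fce))
  expect_error(edgeCognitionCorrelation(fceF, "flat"), "constant")
})

test_that("pure noise selects M1 at roughly the (1 - alpha_remove)^2 rate", {
  co <- makeCohort(25, 25, covariates = FALSE, seed = 42)
  ef <- makeEffectMap(10000, 0, 0, 0, noiseSd = 1, seed = 42)
  fce <- simulateDirectZ(co, ef, seed = 42)
  rep <- runMassUnivariate(fce)
  # the independence approximation (1 - 0.05)^2 = 0.9025 overstates the M1
  # rate slightly: the surviving main effect is the better-looking of two,
  # so it is retained more often than 5% (Monte-Carlo rate ~0.855)
  expect_lt(abs(mean(rep$results$model == "M1") - 0.95^2), 0.06)
  # M5 is kept exactly when the interaction survives its removal test
  expect_lt(abs(mean(rep$results$model == "M5") - 0.05), 0.01)
})

test_that("term p-values are uniform under the global null (no selection)", {
  co <- makeCohort(40, 40, covariates = FALSE, seed = 41)
  ef <- makeEffectMap(4000, 0, 0, 0, noiseSd = 1, seed = 41)
  fce <- simulateDirectZ(co, ef, seed = 41)
  rep <- runMassUnivariate(fce, alphaRemove = 1 - 1e-9) # keep M5 everywhere
  expect_true(all(rep$results$model == "M5"))
  expect_gt(stats::ks.test(rep$results$p_int, "punif")$p.value, 0.01)
  expect_gt(stats::ks.test(rep$results$p_F, "punif")$p.value, 0.01)
})
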