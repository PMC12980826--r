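test_that("zeta sign split routes each sign to its own variable", {
  z <- splitZeta(37.2)
  expect_equal(unlist(z), c(zeta_pos_mV = 37.2, zeta_neg_mV = 0))
  z <- splitZeta(-61.7)
  expect_equal(unlist(z), c(zeta_pos_mV = 0, zeta_neg_mV = 61.7))
  expect_equal(unlist(splitZeta(0)), c(zeta_pos_mV = 0, zeta_neg_mV = 0))
  # signed encoding keeps the negative sign
  zs <- splitZeta(-61.7, "signed")
  expect_equal(zs$zeta_neg_mV, -61.7)
  # invariants: at most one nonzero; signed value reconstructable
  set.seed(8)
  zz <- stats::runif(50, -90, 40)
  sp <- splitZeta(zz)
  expect_true(all(sp$zeta_pos_mV * sp$zeta_neg_mV == 0))
  expect_equal(sp$zeta_pos_mV - sp$zeta_neg_mV, zz)
})

test_that("design matrices have the variant columns over the 24-row panel", {
  panel <- simulatePanel(panelSpec(seed = 2))
  dFinal <- buildDesign(panel$conditions, panel$descriptors, "final")
  expect_equal(dim(dFinal$X), c(24L, 5L))
  expect_equal(colnames(dFinal$X),
               c("theta_deg", "zeta_pos_mV", "zeta_neg_mV",
                 "sasa_hydrophobic", "sasa_hydrophilic"))
  dS1 <- buildDesign(panel$conditions, variant = "S1")
  expect_equal(dim(dS1$X), c(24L, 2L))
  dS2 <- buildDesign(panel$conditions, variant = "S2")
  expect_equal(dim(dS2$X), c(24L, 3L))

  bad <- panel$conditions
  bad$serotype[1] <- "sim01"; bad$serotype[2] <- "sim01"
  bad$surface_id[2] <- bad$surface_id[1]; bad$buffer_id[2] <- bad$buffer_id[1]
  expect_error(buildDesign(bad, panel$descriptors, "final"), "duplicate")
  orphan <- panel$conditions
  orphan$serotype[5] <- "unknown99"
  expect_error(buildDesign(orphan, panel$descriptors, "final"), "unknown99")
})

test_that("OLS matches the normal-equations oracle on random designs", {
  set.seed(99)
  for (i in 1:100) {
    n <- sample(10:30, 1); k <- sample(2:4, 1)
    prob <- randomDesign(n, k)
    fit <- fitAdsorptionModel(X = prob$X, y = prob$y)
    oracle <- olsOracle(prob$X, prob$y)
    expect_equal(unname(fit@coefficients), unname(oracle$beta),
                 tolerance = 1e-8)
    expect_equal(unname(fit@standardErrors), unname(oracle$se),
                 tolerance = 1e-8)
    expect_equal(unname(fit@tValues), unname(oracle$t), tolerance = 1e-8)
    expect_equal(unname(fit@pValues), unname(oracle$p), tolerance = 1e-8)
    expect_equal(fit@rSquared, oracle$r2, tolerance = 1e-8)
    # pseudo-inverse equivalence route
    expect_equal(unname(fit@coefficients), pinvSolve(prob$X, prob$y),
                 tolerance = 1e-8)
  }
})

test_that("degenerate fits behave as defined", {
  X <- cbind(a = c(1, 2, 3, 4, 5, 6))
  yLin <- 2 + 3 * X[, 1]
  fit <- fitAdsorptionModel(X = X, y = yLin)
  expect_equal(fit@rSquared, 1, tolerance = 1e-12)
  expect_equal(max(abs(fit@residuals)), 0, tolerance = 1e-10)

  yConst <- rep(7, 6)
  fitC <- fitAdsorptionModel(X = X, y = yConst)
  expect_equal(unname(fitC@coefficients), c(7, 0), tolerance = 1e-12)
  expect_equal(fitC@rSquared, 0)

  Xs <- cbind(a = 1:8, b = 2 * (1:8))
  expect_error(fitAdsorptionModel(X = Xs, y = stats::rnorm(8)),
               "collinear")
})

test_that("standardized coefficients obey the rescaling identity", {
  set.seed(12)
  prob <- randomDesign(24, 4)
  fit <- fitAdsorptionModel(X = prob$X, y = prob$y)
  refit <- standardizedFit(prob$X, prob$y)
  identity <- fit@coefficients[-1] * apply(prob$X, 2, stats::sd) /
    stats::sd(prob$y)
  expect_equal(unname(standardizedCoefficients(fit)), unname(identity),
               tolerance = 1e-10)
  expect_equal(unname(refit@coefficients[-1]), unname(identity),
               tolerance = 1e-10)
  # one predictor: the standardized slope is the Pearson correlation
  one <- fitAdsorptionModel(X = prob$X[, 1, drop = FALSE], y = prob$y)
  expect_equal(unname(standardizedCoefficients(one)),
               stats::cor(prob$X[, 1], prob$y), tolerance = 1e-10)
  expect_error(standardizedFit(cbind(v = rep(1, 10)), stats::rnorm(10)),
               "zero-variance")
})

test_that("standardized magnitudes rank the generating model's dominant terms", {
  panel <- simulatePanel(panelSpec(noiseSd = 1, seed = 13))
  fit <- fitAdsorptionModel(
    buildDesign(panel$conditions, panel$descriptors, "final"))
  std <- standardizedCoefficients(fit)
  # zeta_pos and theta dominate the generating model on this layout
  expect_setequal(names(sort(abs(std), decreasing = TRUE))[1:2],
                  c("zeta_pos_mV", "theta_deg"))
})

test_that("prediction reproduces fitted values and the intercept case", {
  panel <- simulatePanel(panelSpec(noiseSd = 0, seed = 3))
  design <- buildDesign(panel$conditions, panel$descriptors, "final")
  fit <- fitAdsorptionModel(design)
  pr <- predict(fit, as.data.frame(design$X))
  expect_equal(pr$raw_percent, fit@fitted, tolerance = 1e-10)
  # noiseless panel: predictions equal the generating values
  expect_equal(pr$raw_percent, panel$conditions$response_true,
               tolerance = 1e-8)
  zero <- as.data.frame(matrix(0, 1, 5,
    dimnames = list(NULL, colnames(design$X))))
  expect_equal(predict(fit, zero)$raw_percent,
               unname(fit@coefficients[1]), tolerance = 1e-10)
  expect_error(predict(fit, zero[, -2, drop = FALSE]), "zeta_pos_mV")
  # clamping only affects out-of-range raw values
  far <- zero; far$theta_deg <- 1e4
  p2 <- predict(fit, far)
  expect_gt(p2$raw_percent, 100)
  expect_equal(p2$clamped_percent, 100)
})

test_that("validation R-squared definitions behave as documented", {
  obs <- c(10, 30, 50, 70)
  expect_equal(validationR2(obs, obs), 1)
  expect_equal(validationR2(obs, obs, "one_minus_ssres"), 1)
  expect_error(validationR2(obs, rep(5, 4)), "constant")
  expect_lte(validationR2(obs, rep(5, 4), "one_minus_ssres"), 0)
  expect_error(validationR2(rep(1, 4), obs), "zero variance")
  set.seed(77)
  o <- stats::rnorm(20); p <- o + stats::rnorm(20, 0, 0.5)
  expect_equal(validationR2(o, p), stats::cor(o, p)^2, tolerance = 1e-12)
  expect_equal(validationR2(o, p, "one_minus_ssres"),
               1 - sum((o - p)^2) / sum((o - mean(o))^2),
               tolerance = 1e-12)
})

test_that("nested variants have non-decreasing R-squared", {
  for (seed in c(1, 5, 11, 23)) {
    panel <- simulatePanel(panelSpec(noiseSd = 3, seed = seed))
    r2 <- vapply(c("S1", "S2", "final"), function(v)
      rSquared(fitAdsorptionModel(
        buildDesign(panel$conditions, panel$descriptors, v))), numeric(1))
    expect_true(all(diff(r2) >= -1e-12))
  }
})
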