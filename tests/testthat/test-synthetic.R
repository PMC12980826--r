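test_that("panel generation is a pure function of its spec", {
  a <- simulatePanel(panelSpec(seed = 42))
  b <- simulatePanel(panelSpec(seed = 42))
  expect_identical(a, b)
  c_ <- simulatePanel(panelSpec(seed = 43))
  expect_false(identical(a$conditions$response_percent,
                         c_$conditions$response_percent))
  # the generator does not disturb the caller's RNG stream
  set.seed(1); x1 <- stats::rnorm(1)
  set.seed(1); invisible(simulatePanel(panelSpec(seed = 9)))
  x2 <- stats::rnorm(1)
  expect_identical(x1, x2)
})

test_that("the default panel matches the screening-campaign layout", {
  p <- simulatePanel(panelSpec())
  expect_equal(nrow(p$conditions), 24L)    # 4 serotypes x 3 surfaces x 2
  expect_equal(nrow(p$observations), 72L)  # triplicates
  expect_equal(nrow(p$descriptors), 4L)
  expect_true(all(p$conditions$theta_deg >= 20 &
                  p$conditions$theta_deg <= 100))
  expect_true(all(p$conditions$zeta_mV >= -90 &
                  p$conditions$zeta_mV <= 40))
  expect_true(all(p$descriptors$sasa_hydrophobic >= 1e5 &
                  p$descriptors$sasa_hydrophobic <= 6e5))
  expect_true(all(p$descriptors$sasa_hydrophilic >= 1e5 &
                  p$descriptors$sasa_hydrophilic <= 6e5))
  expect_equal(p$descriptors$sasa_hydrophilic,
               p$descriptors$sasa_acidic + p$descriptors$sasa_basic)
  # responses observable and clamping rare under the default conditions
  expect_true(all(p$conditions$response_percent >= 0 &
                  p$conditions$response_percent <= 100))
  expect_lt(p$clampFraction, 0.1)
})

test_that("titer observations reproduce the generated ratios", {
  p <- simulatePanel(panelSpec(seed = 6))
  r <- adsorptionRatio(p$observations$titer_before_vg_ml,
                       p$observations$titer_after_vg_ml)
  agg <- summarizeAdsorption(p$observations)
  key <- paste(p$conditions$serotype, p$conditions$surface_id,
               p$conditions$buffer_id)
  idx <- match(key, paste(agg$serotype, agg$surface_id, agg$buffer_id))
  expect_equal(agg$mean_percent[idx], p$conditions$response_percent,
               tolerance = 1e-9)
  expect_true(all(r >= 0 & r <= 100))
})

test_that("noiseless panels identify the generating coefficients", {
  p <- simulatePanel(panelSpec(noiseSd = 0, seed = 12))
  fit <- fitAdsorptionModel(buildDesign(p$conditions, p$descriptors,
                                        "final"))
  expect_equal(unname(fit@coefficients), unname(p$betaTrue),
               tolerance = 1e-8)
  expect_equal(rSquared(fit), 1, tolerance = 1e-10)
})

test_that("coefficient sampling spread matches OLS theory", {
  # single-replicate panels so the response noise sd is the spec value
  nrep <- 400
  betas <- matrix(NA_real_, nrep, 6)
  X1 <- NULL
  for (i in seq_len(nrep)) {
    p <- simulatePanel(panelSpec(noiseSd = 1, replicates = 1L,
                                 seed = 1000 + i))
    d <- buildDesign(p$conditions, p$descriptors, "final")
    if (i == 1) X1 <- cbind(1, d$X)
    betas[i, ] <- fitAdsorptionModel(d)@coefficients
  }
  # theta and the zeta split are fixed across seeds; only the SASA columns
  # vary, so compare the empirical sd of their slopes against the formula
  # sd from a representative design
  sdTheory <- sqrt(diag(solve(crossprod(X1))))  # sigma = 1
  sdEmp <- apply(betas, 2, stats::sd)
  for (j in 2:4)   # theta, zeta_pos, zeta_neg: identical design columns
    expect_equal(sdEmp[j], unname(sdTheory[j]), tolerance = 0.1)
})

test_that("toy capsids respect separation and shell geometry", {
  toy <- generateToyCapsid(nCopies = 12, atomsPerCopy = 12, seed = 3)
  s <- toy$structure
  expect_s4_class(s, "CapsidStructure")
  expect_equal(s@transforms[[1]], cbind(diag(3), c(0, 0, 0)))
  a <- expandAssembly(s)
  # every pair of assembly atoms farther apart than 2*(vdw+probe): the
  # no-occlusion guarantee behind the analytic ground truth
  expect_gt(min(stats::dist(as.matrix(a@atoms[, c("x", "y", "z")]))),
            2 * (1.7 + 1.4))
  expect_setequal(unique(toy$groundTruth$shell), c("outer", "inner"))
  expect_equal(sort(unique(round(toy$groundTruth$radius))),
               c(60, 115), tolerance = 0.5)
})

test_that("toy ground truth covers the all-inner and mixed cases", {
  allIn <- generateToyCapsid(nCopies = 6, atomsPerCopy = 8,
                             innerFraction = 1, innerRadius = 60,
                             shellRadius = 115, seed = 2)
  want <- allIn$expectedOuter(105)
  expect_equal(unname(want[c("hydrophobic", "acidic", "basic")]),
               c(0, 0, 0))
  res <- suppressWarnings(capsidDescriptor(allIn$structure, nPoints = 240))
  expect_equal(res@sasaHydrophobic + res@sasaAcidic + res@sasaBasic, 0)

  mixed <- generateToyCapsid(nCopies = 8, atomsPerCopy = 10,
                             innerFraction = 0.4, seed = 15)
  wantM <- mixed$expectedOuter(105)
  # counts x isolated-sphere area, straight from the truth table
  iso <- mixed$isolatedArea
  tally <- table(factor(mixed$groundTruth$category[
    mixed$groundTruth$shell == "outer"],
    levels = c("hydrophobic", "acidic", "basic", "unclassified")))
  expect_equal(unname(wantM["hydrophobic"]),
               unname(tally["hydrophobic"]) * iso, tolerance = 1e-9)
  expect_equal(unname(wantM["acidic"]), unname(tally["acidic"]) * iso,
               tolerance = 1e-9)
})

test_that("impossible placements error after retrying", {
  expect_error(
    generateToyCapsid(nCopies = 2, atomsPerCopy = 400, shellRadius = 20,
                      innerFraction = 0, innerRadius = 10, seed = 1),
    "separation")
})

test_that("sphere clusters expose analytic SASA where closed forms exist", {
  one <- makeSphereCluster(matrix(0, 1, 3), 1.7)
  expect_equal(one$analytic, 4 * pi * 3.1^2)
  expect_equal(one$oracle, "closed form")
  two <- makeSphereCluster(rbind(c(0, 0, 0), c(10, 0, 0)), c(1.7, 1.7))
  expect_equal(two$analytic, rep(4 * pi * 3.1^2, 2))
  overlap <- makeSphereCluster(rbind(c(0, 0, 0), c(2, 0, 0)), c(1.7, 1.7))
  expect_equal(overlap$analytic,
               rep(4 * pi * 3.1^2 - 2 * pi * 3.1 * 2.1, 2))
  # overlapping triple: no closed form
  tri <- makeSphereCluster(rbind(c(0, 0, 0), c(2, 0, 0), c(1, 1.5, 0)),
                           rep(1.7, 3))
  expect_true(all(is.na(tri$analytic)))
  expect_equal(tri$oracle, "numeric only")
})
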