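test_that("residue classification follows the category lists", {
  expect_equal(classifyResidue(c("PHE", "ILE", "LEU", "TYR", "TRP", "VAL",
                                 "MET", "PRO", "CYS", "ALA")),
               rep("hydrophobic", 10))
  expect_equal(classifyResidue(c("ASP", "GLU")), rep("acidic", 2))
  expect_equal(classifyResidue(c("LYS", "ARG")), rep("basic", 2))
  expect_equal(classifyResidue(c("SER", "THR", "ASN", "GLN", "HIS", "GLY")),
               rep("unclassified", 6))
  expect_message(out <- classifyResidue("XYZ"), "unrecognised")
  expect_equal(out, "unclassified")
})

.oneAtomHood <- function(dist, resid = "LEU", sidechain = TRUE) {
  h <- data.frame(eleno = 1L, elety = if (sidechain) "CB" else "CA",
                  resid = resid, resno = 1L, chain = "A",
                  x = dist, y = 0, z = 0, element = "C", vdw = 1.7,
                  sidechain = sidechain, copy = 0L)
  attr(h, "referenceCopy") <- 0L
  h
}

test_that("the radial filter is strictly 'more than' the threshold", {
  at <- suppressWarnings(
    outerSidechainSasa(.oneAtomHood(105.0), center = c(0, 0, 0),
                       perAtomSasa = 10, radialThreshold = 105))
  expect_equal(at@sasaHydrophobic, 0)
  expect_equal(at@nAtomsOuter, 0L)
  beyond <- outerSidechainSasa(.oneAtomHood(106), center = c(0, 0, 0),
                               perAtomSasa = 10, radialThreshold = 105)
  expect_equal(beyond@sasaHydrophobic, 10)
  expect_equal(beyond@nAtomsOuter, 1L)
})

test_that("backbone atoms and unclassified residues contribute nothing", {
  bb <- suppressWarnings(
    outerSidechainSasa(.oneAtomHood(110, sidechain = FALSE), c(0, 0, 0),
                       perAtomSasa = 10))
  expect_equal(bb@nAtomsOuter, 0L)
  ser <- outerSidechainSasa(.oneAtomHood(110, resid = "SER"), c(0, 0, 0),
                            perAtomSasa = 10)
  expect_equal(ser@nAtomsOuter, 1L)
  expect_equal(ser@sasaHydrophobic + ser@sasaAcidic + ser@sasaBasic, 0)
})

test_that("category sums match a brute-force tally on toy capsids", {
  for (seed in c(3, 17)) {
    toy <- generateToyCapsid(nCopies = 12, atomsPerCopy = 12, seed = seed)
    a <- expandAssembly(toy$structure)
    hood <- withCallingHandlers(
      selectNeighborhood(a, 0L, 6),
      warning = function(w) invokeRestart("muffleWarning"))
    sasa <- shrakeRupleySasa(as.matrix(hood[, c("x", "y", "z")]),
                             hood$vdw, nPoints = 480)
    res <- outerSidechainSasa(hood, a@center, sasa, radialThreshold = 105)
    oracle <- bruteForceOuterTally(hood, a@center, 105, sasa, 0L)
    expect_equal(res@sasaHydrophobic, unname(oracle$sums["hydrophobic"]),
                 tolerance = 1e-12)
    expect_equal(res@sasaAcidic, unname(oracle$sums["acidic"]),
                 tolerance = 1e-12)
    expect_equal(res@sasaBasic, unname(oracle$sums["basic"]),
                 tolerance = 1e-12)
    expect_equal(res@nAtomsOuter, oracle$nOuter)
    # identity by construction, and preserved through the class validity
    expect_identical(res@sasaHydrophilic, res@sasaAcidic + res@sasaBasic)
  }
})

test_that("category sums never exceed the total outer side-chain SASA", {
  toy <- generateToyCapsid(nCopies = 12, atomsPerCopy = 16, seed = 21)
  a <- expandAssembly(toy$structure)
  hood <- withCallingHandlers(
    selectNeighborhood(a, 0L, 6),
    warning = function(w) invokeRestart("muffleWarning"))
  sasa <- shrakeRupleySasa(as.matrix(hood[, c("x", "y", "z")]),
                           hood$vdw, nPoints = 480)
  res <- outerSidechainSasa(hood, a@center, sasa)
  d <- sqrt((hood$x - a@center[1])^2 + (hood$y - a@center[2])^2 +
            (hood$z - a@center[3])^2)
  total <- sum(sasa[hood$copy == 0L & hood$sidechain & d > 105])
  expect_lte(res@sasaHydrophobic + res@sasaAcidic + res@sasaBasic,
             total + 1e-9)
})

test_that("the full descriptor path reproduces the analytic ground truth", {
  toy <- generateToyCapsid(nCopies = 12, atomsPerCopy = 12, seed = 4)
  res <- suppressWarnings(
    capsidDescriptor(toy$structure, serotype = "toy", nPoints = 480))
  want <- toy$expectedOuter(105)
  expect_equal(res@sasaHydrophobic, unname(want["hydrophobic"]),
               tolerance = 1e-9)
  expect_equal(res@sasaAcidic, unname(want["acidic"]), tolerance = 1e-9)
  expect_equal(res@sasaBasic, unname(want["basic"]), tolerance = 1e-9)
  expect_equal(res@nAtomsOuter, as.integer(want["n_outer"]))
})

test_that("acidic/basic correlation matches the covariance formula", {
  d <- data.frame(sasa_acidic = c(1, 2, 3, 4), sasa_basic = c(1, 2, 3, 4))
  expect_equal(acidicBasicCorrelation(d), 1)
  d2 <- data.frame(sasa_acidic = c(1, 2, 3, 4),
                   sasa_basic = 10 - c(1, 2, 3, 4))
  expect_equal(acidicBasicCorrelation(d2), -1)
  set.seed(5)
  a <- stats::runif(4, 1e5, 3e5); b <- stats::runif(4, 1e5, 3e5)
  manual <- sum((a - mean(a)) * (b - mean(b))) /
    sqrt(sum((a - mean(a))^2) * sum((b - mean(b))^2))
  expect_equal(acidicBasicCorrelation(
    data.frame(sasa_acidic = a, sasa_basic = b)), manual,
    tolerance = 1e-12)
  expect_error(acidicBasicCorrelation(
    data.frame(sasa_acidic = c(1, 1, 1), sasa_basic = c(1, 2, 3))),
    "zero variance")
  expect_error(acidicBasicCorrelation(
    data.frame(sasa_acidic = c(1, 2), sasa_basic = c(1, 2))), "at least 3")
})
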