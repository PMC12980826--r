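# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: plain loops, normal equations, closed forms.

# all-pairs distance scan: which copies have any atom within cutoff of any
# reference-copy atom
bruteForceNeighborCopies <- function(assembly, refCopy, cutoff) {
  a <- assembly@atoms
  ref <- a[a$copy == refCopy, c("x", "y", "z")]
  hits <- integer(0)
  for (cp in setdiff(unique(a$copy), refCopy)) {
    blk <- a[a$copy == cp, c("x", "y", "z")]
    found <- FALSE
    for (i in seq_len(nrow(ref))) {
      d <- sqrt((blk$x - ref$x[i])^2 + (blk$y - ref$y[i])^2 +
                (blk$z - ref$z[i])^2)
      if (any(d <= cutoff)) { found <- TRUE; break }
    }
    if (found) hits <- c(hits, cp)
  }
  sort(hits)
}

# loop-based per-category tally of outer side-chain SASA
bruteForceOuterTally <- function(hood, center, threshold, sasa, refCopy) {
  sums <- c(hydrophobic = 0, acidic = 0, basic = 0)
  nOuter <- 0L
  hydro <- c("PHE", "ILE", "LEU", "TYR", "TRP", "VAL", "MET", "PRO",
             "CYS", "ALA")
  for (i in seq_len(nrow(hood))) {
    if (hood$copy[i] != refCopy) next
    if (!hood$sidechain[i]) next
    d <- sqrt(sum((c(hood$x[i], hood$y[i], hood$z[i]) - center)^2))
    if (d <= threshold) next
    nOuter <- nOuter + 1L
    r <- hood$resid[i]
    if (r %in% hydro) sums["hydrophobic"] <- sums["hydrophobic"] + sasa[i]
    else if (r %in% c("ASP", "GLU")) sums["acidic"] <- sums["acidic"] + sasa[i]
    else if (r %in% c("LYS", "ARG")) sums["basic"] <- sums["basic"] + sasa[i]
  }
  list(sums = sums, nOuter = nOuter)
}

# textbook normal-equations OLS with t-distribution inference
olsOracle <- function(X, y) {
  Xi <- cbind(1, as.matrix(X))
  XtX <- t(Xi) %*% Xi
  beta <- solve(XtX, t(Xi) %*% y)
  res <- y - Xi %*% beta
  df <- nrow(Xi) - ncol(Xi)
  sigma2 <- sum(res^2) / df
  se <- sqrt(diag(sigma2 * solve(XtX)))
  tv <- drop(beta) / se
  pv <- 2 * stats::pt(-abs(tv), df)
  r2 <- 1 - sum(res^2) / sum((y - mean(y))^2)
  list(beta = drop(beta), se = se, t = tv, p = pv, r2 = r2)
}

# Moore-Penrose solve via SVD (equivalence route)
pinvSolve <- function(X, y) {
  Xi <- cbind(1, as.matrix(X))
  s <- svd(Xi)
  drop(s$v %*% ((t(s$u) %*% y) / s$d))
}

# random well-posed cluster of atoms for SASA property tests
randomCluster <- function(n, spread = 4, rmin = 1.4, rmax = 1.9) {
  repeat {
    pos <- matrix(stats::runif(n * 3, -spread, spread), n, 3)
    if (n == 1 || min(stats::dist(pos)) > 0.5) break
  }
  list(pos = pos, radii = stats::runif(n, rmin, rmax))
}

# small random regression problem
randomDesign <- function(n, k) {
  X <- matrix(stats::rnorm(n * k), n, k,
              dimnames = list(NULL, paste0("v", seq_len(k))))
  y <- drop(X %*% stats::rnorm(k)) + stats::rnorm(n)
  list(X = X, y = y)
}

# minimal two-atom PDB text with an identity + rotation BIOMT block
writeMiniPdb <- function(file) {
  lines <- c(
    "REMARK 350 BIOMOLECULE: 1",
    "REMARK 350 APPLY THE FOLLOWING TO CHAINS: A",
    "REMARK 350   BIOMT1   1  1.000000  0.000000  0.000000        0.00000",
    "REMARK 350   BIOMT2   1  0.000000  1.000000  0.000000        0.00000",
    "REMARK 350   BIOMT3   1  0.000000  0.000000  1.000000        0.00000",
    "ATOM      1  CA  GLY A   1       1.000   0.000   0.000  1.00  0.00           C",
    "ATOM      2  CB  ALA A   2       2.000   1.000   0.000  1.00  0.00           C",
    "END")
  writeLines(lines, file)
  file
}
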