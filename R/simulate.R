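# Synthetic-data generators: adsorption panels with known regression
# coefficients, and toy capsid shells with analytic outer-SASA ground
# truth. Every generator is a pure function of its spec (including the
# seed): the RNG state is saved and restored around each call.

.withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv(),
                          inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  force(expr)
}

#' Default surface panel: one hydrophobic and two hydrophilic surfaces
#'
#' Contact angles and zeta potentials (in a low-ionic-strength reference
#' solvent) spanning hydrophobic/negative, hydrophilic/negative and
#' hydrophilic/positive character, the design space over which the
#' adsorption model is identified.
#'
#' @return data.frame with `surface_id`, `theta_deg`, `zeta_mV`
#' @export
defaultSurfacePanel <- function() {
  data.frame(surface_id = c("hydrophobic_neg", "hydrophilic_neg",
                            "hydrophilic_pos"),
             theta_deg = c(90, 30, 30),
             zeta_mV = c(-85.9, -61.7, 37.2),
             stringsAsFactors = FALSE)
}

#' Default generating coefficients for simulated panels
#'
#' Intercept, contact angle, positive zeta, negative zeta (magnitude
#' encoding), hydrophobic SASA and hydrophilic SASA slopes on the percent
#' response scale. These are a simulation default shaped like published
#' rAAV adsorption fits, not ground truth about any real serotype.
#'
#' @return named numeric 6-vector
#' @export
defaultBetaTrue <- function() {
  c(`(Intercept)` = 0.41, theta_deg = 0.32, zeta_pos_mV = 2.47,
    zeta_neg_mV = -0.42, sasa_hydrophobic = -2.587e-4,
    sasa_hydrophilic = 8.661e-5)
}

#' Specification of a simulated adsorption panel
#'
#' Describes a serotype x surface x ionic-strength panel whose response is
#' generated from the final adsorption model plus i.i.d. Gaussian noise,
#' clamped to the observable [0, 100] percent window. The default layout
#' (4 pseudo-serotypes x 3 surfaces x 2 ionic conditions = 24 conditions,
#' triplicate observations) mirrors a surfactant-free screening campaign.
#' Zeta potentials at the two ionic conditions are the reference-solvent
#' values attenuated by `screening` (double-layer compression at 200 and
#' 350 mM salt). SASA descriptors are drawn uniformly inside windows
#' chosen so that the linear predictor stays inside [0, 100] and clamping
#' remains rare.
#'
#' @param nSerotypes number of pseudo-serotypes
#' @param surfaces data.frame as [defaultSurfacePanel()]
#' @param ionicConditions number of ionic-strength conditions
#' @param screening zeta attenuation factor per ionic condition (length
#'   `ionicConditions`)
#' @param betaTrue named 6-vector of generating coefficients (percent
#'   scale), order as [defaultBetaTrue()]
#' @param noiseSd Gaussian noise sd on the replicate ratio, percentage
#'   points (>= 0)
#' @param replicates observations per condition (>= 1)
#' @param seed RNG seed
#' @param titerBefore nominal pre-adsorption titer, vg/mL
#' @param sasaHydrophobicRange,sasaHydrophilicRange uniform draw windows,
#'   A^2
#' @return list of class `panelSpec`
#' @export
panelSpec <- function(nSerotypes = 4L,
                      surfaces = defaultSurfacePanel(),
                      ionicConditions = 2L,
                      screening = c(0.29, 0.17),
                      betaTrue = defaultBetaTrue(),
                      noiseSd = 2, replicates = 3L, seed = 1L,
                      titerBefore = 5.5e10,
                      sasaHydrophobicRange = c(1.0e5, 1.2e5),
                      sasaHydrophilicRange = c(3.4e5, 5.2e5)) {
  stopifnot(nSerotypes >= 1L, nrow(surfaces) >= 1L,
            ionicConditions >= 1L,
            length(screening) == ionicConditions,
            length(betaTrue) == 6L, noiseSd >= 0, replicates >= 1L,
            titerBefore > 0)
  structure(list(nSerotypes = as.integer(nSerotypes), surfaces = surfaces,
                 ionicConditions = as.integer(ionicConditions),
                 screening = screening, betaTrue = betaTrue,
                 noiseSd = noiseSd, replicates = as.integer(replicates),
                 seed = as.integer(seed), titerBefore = titerBefore,
                 sasaHydrophobicRange = sasaHydrophobicRange,
                 sasaHydrophilicRange = sasaHydrophilicRange),
            class = "panelSpec")
}

#' Simulate an adsorption panel with known coefficients
#'
#' Draws per-serotype SASA descriptors (acidic and basic components split
#' near-evenly so their correlation across serotypes is strong, as for
#' real capsids), evaluates the generating linear model at every
#' serotype x surface x ionic condition, adds Gaussian noise per
#' replicate, clamps to [0, 100]%, and back-computes replicate titers
#' around the nominal pre-titer so the titer-level statistics can be
#' exercised end to end.
#'
#' @param spec a [panelSpec()]
#' @return list with `conditions` (one row per condition; the
#'   `response_percent` column is the replicate mean, `response_true` the
#'   noiseless linear predictor), `observations` (one row per replicate
#'   with titers), `descriptors` (per-serotype SASA table),
#'   `betaTrue`, and `clampFraction` (fraction of replicate draws that
#'   hit a clamp; heavy clamping biases recovery)
#' @examples
#' panel <- simulatePanel(panelSpec(noiseSd = 0))
#' head(panel$conditions)
#' @export
simulatePanel <- function(spec = panelSpec()) {
  stopifnot(inherits(spec, "panelSpec"))
  .withSeed(spec$seed, {
    sero <- sprintf("sim%02d", seq_len(spec$nSerotypes))
    sphob <- stats::runif(spec$nSerotypes, spec$sasaHydrophobicRange[1],
                          spec$sasaHydrophobicRange[2])
    sphil <- stats::runif(spec$nSerotypes, spec$sasaHydrophilicRange[1],
                          spec$sasaHydrophilicRange[2])
    # near-even acidic/basic split: strongly correlated components
    frac <- stats::runif(spec$nSerotypes, 0.48, 0.52)
    descriptors <- data.frame(serotype = sero,
                              sasa_hydrophobic = sphob,
                              sasa_acidic = frac * sphil,
                              sasa_basic = (1 - frac) * sphil,
                              sasa_hydrophilic = sphil,
                              stringsAsFactors = FALSE)

    grid <- expand.grid(serotype = sero,
                        surface_id = spec$surfaces$surface_id,
                        ionic = seq_len(spec$ionicConditions),
                        KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    si <- match(grid$surface_id, spec$surfaces$surface_id)
    di <- match(grid$serotype, descriptors$serotype)
    theta <- spec$surfaces$theta_deg[si]
    zeta <- spec$surfaces$zeta_mV[si] * spec$screening[grid$ionic]
    zs <- splitZeta(zeta, "magnitude")
    b <- spec$betaTrue
    mu <- b[1] + b[2] * theta + b[3] * zs$zeta_pos_mV +
      b[4] * zs$zeta_neg_mV + b[5] * descriptors$sasa_hydrophobic[di] +
      b[6] * descriptors$sasa_hydrophilic[di]

    nC <- nrow(grid)
    reps <- spec$replicates
    raw <- rep(mu, each = reps) +
      if (spec$noiseSd > 0) stats::rnorm(nC * reps, 0, spec$noiseSd)
      else 0
    ratio <- pmin(100, pmax(0, raw))
    clampFraction <- mean(raw != ratio)

    observations <- data.frame(
      serotype = rep(grid$serotype, each = reps),
      surface_id = rep(grid$surface_id, each = reps),
      buffer_id = rep(paste0("ionic", grid$ionic), each = reps),
      replicate = rep(seq_len(reps), times = nC),
      titer_before_vg_ml = spec$titerBefore,
      titer_after_vg_ml = spec$titerBefore * (1 - ratio / 100),
      stringsAsFactors = FALSE)

    conditions <- data.frame(
      serotype = grid$serotype, surface_id = grid$surface_id,
      buffer_id = paste0("ionic", grid$ionic),
      theta_deg = theta, zeta_mV = zeta,
      response_percent = colMeans(matrix(ratio, nrow = reps)),
      response_true = unname(mu), stringsAsFactors = FALSE)

    list(conditions = conditions, observations = observations,
         descriptors = descriptors, betaTrue = b,
         clampFraction = clampFraction)
  })
}

#' Specification of a toy capsid shell
#'
#' Pseudo-atoms (one side-chain atom per pseudo-residue) arranged in
#' well-separated patches on a spherical shell, one patch per symmetry
#' copy; a fraction of atoms is placed on an inner shell below the radial
#' threshold to exercise the outer-surface filter. Atoms are kept farther
#' apart than `2 * (vdw + probe)`, so every atom's SASA is exactly the
#' isolated-sphere area and per-category sums are known by construction.
#'
#' @param nCopies symmetry copies (the icosahedral case is 60)
#' @param shellRadius outer-shell radius, Angstrom
#' @param atomsPerCopy pseudo-residues per copy
#' @param categoryFractions simplex over hydrophobic/acidic/basic/
#'   unclassified
#' @param innerFraction fraction of atoms placed on the inner shell
#' @param innerRadius inner-shell radius, Angstrom
#' @param vdw van der Waals radius of every pseudo-atom, Angstrom
#' @param seed RNG seed
#' @return list of class `toyCapsidSpec`
#' @export
toyCapsidSpec <- function(nCopies = 12L, shellRadius = 115,
                          atomsPerCopy = 12L,
                          categoryFractions = c(hydrophobic = 0.4,
                                                acidic = 0.2, basic = 0.2,
                                                unclassified = 0.2),
                          innerFraction = 0.25, innerRadius = 60,
                          vdw = 1.7, seed = 1L) {
  stopifnot(nCopies >= 1L, shellRadius > 0, atomsPerCopy >= 1L,
            abs(sum(categoryFractions) - 1) < 1e-9,
            all(categoryFractions >= 0),
            innerFraction >= 0, innerFraction <= 1,
            innerRadius > 0, innerRadius < shellRadius, vdw > 0)
  structure(list(nCopies = as.integer(nCopies), shellRadius = shellRadius,
                 atomsPerCopy = as.integer(atomsPerCopy),
                 categoryFractions = categoryFractions,
                 innerFraction = innerFraction, innerRadius = innerRadius,
                 vdw = vdw, seed = as.integer(seed)),
            class = "toyCapsidSpec")
}

.categoryResidue <- c(hydrophobic = "LEU", acidic = "ASP", basic = "LYS",
                      unclassified = "SER")

# rotation taking +z to unit vector d (Rodrigues)
.rotationTo <- function(d) {
  z <- c(0, 0, 1)
  c_ <- sum(z * d)
  if (c_ > 1 - 1e-12) return(diag(3))
  if (c_ < -1 + 1e-12) return(diag(c(1, -1, -1)))
  v <- c(z[2] * d[3] - z[3] * d[2], z[3] * d[1] - z[1] * d[3],
         z[1] * d[2] - z[2] * d[1])
  K <- matrix(c(0, v[3], -v[2], -v[3], 0, v[1], v[2], -v[1], 0), 3, 3)
  diag(3) + K + K %*% K / (1 + c_)
}

#' Generate a toy capsid with analytic outer-SASA ground truth
#'
#' Builds the base copy as a patch of labelled pseudo-atoms around the +z
#' pole (outer shell) plus an inner-shell subset, and the assembly
#' transforms as rotations carrying the patch to near-uniform directions
#' (the first transform is the identity). Placement enforces a minimum
#' pairwise separation of `2 * (vdw + probe)`; if a draw cannot satisfy it
#' the placement is retried and finally errors.
#'
#' @param spec a [toyCapsidSpec()]; individual fields can also be passed
#'   through `...` as overrides of the default spec
#' @param probeRadius probe radius used for the separation guarantee and
#'   the analytic areas, Angstrom
#' @param ... spec overrides forwarded to [toyCapsidSpec()]
#' @return list with `structure` ([CapsidStructure-class]),
#'   `groundTruth` (per base-copy atom: category, shell radius, whether it
#'   lies strictly beyond a threshold is up to the caller), and
#'   `expectedOuter(threshold)` a function returning the exact per-category
#'   outer sums for any radial threshold, computed from the true assembly
#'   centroid and the isolated-sphere area
#' @export
generateToyCapsid <- function(spec = NULL, probeRadius = 1.4, ...) {
  if (is.null(spec)) spec <- toyCapsidSpec(...)
  stopifnot(inherits(spec, "toyCapsidSpec"))
  .withSeed(spec$seed, {
    n <- spec$atomsPerCopy
    nInner <- round(spec$innerFraction * n)
    nOuter <- n - nInner
    minSep <- 2 * (spec$vdw + probeRadius) + 0.1

    # patch of directions in a polar cap; cap size scales with copy count
    # so neighboring patches stay separated
    capAngle <- if (spec$nCopies == 1L) pi / 3 else
      0.35 * acos(1 - 2 / spec$nCopies)
    placeCap <- function(m, radius) {
      for (try in 1:200) {
        u <- stats::runif(m, 0, 1)
        ang <- capAngle * sqrt(u)
        az <- stats::runif(m, 0, 2 * pi)
        pts <- radius * cbind(sin(ang) * cos(az), sin(ang) * sin(az),
                              cos(ang))
        if (m <= 1L || min(stats::dist(pts)) > minSep) return(pts)
      }
      stop("could not place ", m, " atoms at separation ", minSep,
           " A on a shell of radius ", radius,
           "; reduce atomsPerCopy or enlarge the shell")
    }
    outerPts <- placeCap(nOuter, spec$shellRadius)
    coords <- outerPts
    if (nInner > 0) coords <- rbind(coords, placeCap(nInner,
                                                     spec$innerRadius))
    shell <- c(rep("outer", nOuter), rep("inner", nInner))

    cats <- sample(names(spec$categoryFractions), n, replace = TRUE,
                   prob = spec$categoryFractions)
    atoms <- data.frame(
      eleno = seq_len(n), elety = "CB",
      resid = unname(.categoryResidue[cats]), resno = seq_len(n),
      chain = "A", x = coords[, 1], y = coords[, 2], z = coords[, 3],
      element = "C", vdw = spec$vdw, sidechain = TRUE, copy = 0L,
      stringsAsFactors = FALSE)

    dirs <- goldenSpiralPoints(spec$nCopies)
    # pin the first direction to +z exactly: the base patch sits at the
    # pole, so the first transform is the identity
    dirs[1, ] <- c(0, 0, 1)
    transforms <- lapply(seq_len(spec$nCopies), function(i) {
      cbind(.rotationTo(dirs[i, ]), c(0, 0, 0))
    })
    structure_ <- methods::new("CapsidStructure", atoms = atoms,
                               transforms = transforms,
                               source = "toy_capsid")

    groundTruth <- data.frame(resno = atoms$resno, category = cats,
                              shell = shell,
                              radius = sqrt(rowSums(coords^2)),
                              stringsAsFactors = FALSE)
    isoArea <- 4 * pi * (spec$vdw + probeRadius)^2

    assemblyCenter <- {
      asm <- expandAssembly(structure_)
      asm@center
    }
    # exact per-category outer sums for the separated construction; the
    # radial distance is taken from the true assembly centroid
    expectedOuter <- function(threshold) {
      xyz <- as.matrix(atoms[, c("x", "y", "z")])
      d <- sqrt(rowSums(sweep(xyz, 2, assemblyCenter)^2))
      sel <- d > threshold
      out <- vapply(c("hydrophobic", "acidic", "basic"),
                    function(k) sum(sel & cats == k) * isoArea, numeric(1))
      c(out, hydrophilic = out[["acidic"]] + out[["basic"]],
        n_outer = sum(sel))
    }

    list(structure = structure_, groundTruth = groundTruth,
         isolatedArea = isoArea, expectedOuter = expectedOuter,
         assemblyCenter = assemblyCenter)
  })
}

#' Small sphere clusters with analytic SASA where closed forms exist
#'
#' Fixture builder for validating the quadrature engine: returns the atom
#' set together with per-atom analytic SASA from [analyticSasa()] (NA, and
#' an `oracle = "numeric only"` note, where no closed form exists).
#'
#' @param positions n x 3 matrix of centers, Angstrom
#' @param radii vdW radii, Angstrom
#' @param probeRadius probe radius, Angstrom
#' @return list with `positions`, `radii`, `analytic`, `oracle`
#'   ("closed form" or "numeric only")
#' @export
makeSphereCluster <- function(positions, radii, probeRadius = 1.4) {
  positions <- as.matrix(positions)
  stopifnot(nrow(positions) == length(radii))
  analytic <- if (nrow(positions) <= 3L)
    analyticSasa(positions, radii, probeRadius)
  else rep(NA_real_, nrow(positions))
  list(positions = positions, radii = radii, probeRadius = probeRadius,
       analytic = analytic,
       oracle = if (anyNA(analytic)) "numeric only" else "closed form")
}
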