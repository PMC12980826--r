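# Deterministic Shrake-Rupley solvent-accessible surface area.
#
# Each atom is inflated by the probe radius and covered with a fixed
# golden-spiral point set; a point is accessible when it lies outside every
# neighboring inflated sphere. The per-atom SASA is the accessible fraction
# of the inflated sphere area. The point set is a pure function of nPoints,
# so results are fully deterministic.

#' Golden-spiral point set on the unit sphere
#'
#' Deterministic, near-uniform quadrature nodes used by [shrakeRupleySasa()].
#'
#' @param n number of points (>= 1)
#' @return n x 3 matrix of unit vectors
#' @export
goldenSpiralPoints <- function(n) {
  stopifnot(n >= 1)
  k <- seq_len(n)
  z <- 1 - (2 * k - 1) / n
  phi <- k * pi * (3 - sqrt(5))
  s <- sqrt(pmax(0, 1 - z^2))
  cbind(x = s * cos(phi), y = s * sin(phi), z = z)
}

#' Van der Waals radius by element
#'
#' Bondi element radii (Angstrom) for the heavy atoms found in protein
#' crystal structures; unknown elements fall back to the carbon radius with
#' a warning. Hydrogens are not modelled (heavy-atom convention).
#'
#' @param element character vector of element symbols (e.g. "C", "N")
#' @return numeric vector of radii in Angstrom
#' @export
vdwRadius <- function(element) {
  table <- c(C = 1.70, N = 1.55, O = 1.52, S = 1.80, P = 1.80,
             SE = 1.90, F = 1.47, CL = 1.75, BR = 1.85, I = 1.98,
             H = 1.20, D = 1.20)
  el <- toupper(trimws(element))
  r <- unname(table[el])
  if (anyNA(r)) {
    bad <- unique(el[is.na(r)])
    warning("unknown element(s) ", paste(bad, collapse = ", "),
            "; using carbon radius 1.70 A")
    r[is.na(r)] <- 1.70
  }
  r
}

#' Per-atom solvent-accessible surface area (Shrake-Rupley)
#'
#' @param coords n x 3 matrix of atom centers, Angstrom
#' @param radii numeric vdW radii, Angstrom (> 0)
#' @param probeRadius probe sphere radius, Angstrom (>= 0); 1.4 is a water
#'   probe
#' @param nPoints quadrature points per atom (>= 92); 960 gives < 0.5%
#'   error on an isolated sphere
#' @return numeric per-atom SASA in Angstrom^2, each in
#'   `[0, 4*pi*(r + probe)^2]`
#' @examples
#' shrakeRupleySasa(matrix(0, 1, 3), 1.9)          # ~ 4*pi*3.3^2
#' @export
shrakeRupleySasa <- function(coords, radii, probeRadius = 1.4,
                             nPoints = 960L) {
  coords <- as.matrix(coords)
  if (ncol(coords) != 3L) stop("coords must be an n x 3 matrix")
  n <- nrow(coords)
  stopifnot(length(radii) == n, all(radii > 0), probeRadius >= 0,
            nPoints >= 92)
  if (!all(is.finite(coords))) stop("coords must be finite")
  if (n == 0L) return(numeric(0))

  ex <- radii + probeRadius
  pts0 <- goldenSpiralPoints(nPoints)
  # squared distances between centers; test fixtures and VP neighborhoods
  # are small enough (<~5e3 atoms) for the dense matrix
  d2 <- as.matrix(stats::dist(coords))^2

  dup <- which(d2 < 1e-12 & outer(radii, radii, function(a, b) abs(a - b) < 1e-12),
               arr.ind = TRUE)
  dup <- dup[dup[, 1] < dup[, 2], , drop = FALSE]
  if (nrow(dup))
    stop("coincident atom centers with identical radii (atoms ",
         paste(unique(dup[, 1]), collapse = ", "),
         "); deduplicate the input")

  out <- numeric(n)
  for (i in seq_len(n)) {
    nb <- which(d2[i, ] < (ex[i] + ex)^2)
    nb <- nb[nb != i]
    if (length(nb) > 1L) nb <- nb[order(d2[i, nb])]
    free <- rep(TRUE, nPoints)
    if (length(nb)) {
      px <- pts0[, 1] * ex[i] + coords[i, 1]
      py <- pts0[, 2] * ex[i] + coords[i, 2]
      pz <- pts0[, 3] * ex[i] + coords[i, 3]
      for (j in nb) {
        idx <- which(free)
        if (!length(idx)) break
        dj <- (px[idx] - coords[j, 1])^2 + (py[idx] - coords[j, 2])^2 +
              (pz[idx] - coords[j, 3])^2
        free[idx[dj < ex[j]^2]] <- FALSE
      }
    }
    out[i] <- 4 * pi * ex[i]^2 * sum(free) / nPoints
  }
  out
}

#' Analytic SASA for one- and two-sphere configurations
#'
#' Closed-form solvent-accessible areas used as ground truth for the
#' quadrature engine: an isolated sphere has area `4*pi*(r+probe)^2`; for
#' two intersecting inflated spheres each loses a spherical cap
#' (`2*pi*R*h`). Returns NA for configurations without a closed form
#' (overlapping triples, engulfed spheres).
#'
#' @param positions n x 3 matrix (n <= 3 for closed forms)
#' @param radii vdW radii, Angstrom
#' @param probeRadius probe radius, Angstrom
#' @return numeric per-atom analytic SASA, NA where no closed form exists
#' @export
analyticSasa <- function(positions, radii, probeRadius = 1.4) {
  positions <- as.matrix(positions)
  n <- nrow(positions)
  R <- radii + probeRadius
  iso <- 4 * pi * R^2
  if (n == 1L) return(iso)
  d2 <- as.matrix(stats::dist(positions))^2
  overlaps <- d2 < outer(R, R, "+")^2 & upper.tri(d2)
  pairs <- which(overlaps, arr.ind = TRUE)
  area <- iso
  counts <- integer(n)
  for (k in seq_len(nrow(pairs))) {
    i <- pairs[k, 1]; j <- pairs[k, 2]
    d <- sqrt(d2[i, j])
    if (d <= abs(R[i] - R[j])) {         # engulfment: smaller sphere buried
      return(rep(NA_real_, n))
    }
    # cap height on sphere i from the intersection plane
    hi <- R[i] - (d^2 + R[i]^2 - R[j]^2) / (2 * d)
    hj <- R[j] - (d^2 + R[j]^2 - R[i]^2) / (2 * d)
    area[i] <- area[i] - 2 * pi * R[i] * hi
    area[j] <- area[j] - 2 * pi * R[j] * hj
    counts[i] <- counts[i] + 1L
    counts[j] <- counts[j] + 1L
  }
  # caps may themselves intersect when an atom overlaps two others: no
  # closed form there
  if (any(counts > 1L)) return(rep(NA_real_, n))
  area
}

.hydrophobicResidues <- c("PHE", "ILE", "LEU", "TYR", "TRP", "VAL", "MET",
                          "PRO", "CYS", "ALA")
.acidicResidues <- c("ASP", "GLU")
.basicResidues <- c("LYS", "ARG")
.standardResidues <- c(.hydrophobicResidues, .acidicResidues, .basicResidues,
                       "SER", "THR", "ASN", "GLN", "HIS", "GLY")

#' Classify a residue into the adsorption-model categories
#'
#' Hydrophobic: PHE, ILE, LEU, TYR, TRP, VAL, MET, PRO, CYS, ALA.
#' Acidic: ASP, GLU. Basic: LYS, ARG. Everything else (SER, THR, ASN, GLN,
#' HIS, GLY, and non-standard codes) is unclassified and contributes to no
#' SASA category; unknown codes trigger a notice.
#'
#' @param residueName character vector of uppercase 3-letter codes
#' @return character vector in
#'   `c("hydrophobic", "acidic", "basic", "unclassified")`
#' @examples
#' classifyResidue(c("PHE", "ASP", "LYS", "SER"))
#' @export
classifyResidue <- function(residueName) {
  res <- toupper(trimws(residueName))
  out <- rep("unclassified", length(res))
  out[res %in% .hydrophobicResidues] <- "hydrophobic"
  out[res %in% .acidicResidues] <- "acidic"
  out[res %in% .basicResidues] <- "basic"
  unknown <- unique(res[!res %in% .standardResidues])
  if (length(unknown))
    message("unrecognised residue code(s) treated as unclassified: ",
            paste(unknown, collapse = ", "))
  out
}
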