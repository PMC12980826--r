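#' @import methods
NULL

.identity34 <- function() cbind(diag(3), c(0, 0, 0))

# PDB BIOMT records carry 6 decimals, so rotations read back from files
# are orthonormal only to ~1e-5
.isRigidRotation <- function(R, tol = 1e-5) {
  is.matrix(R) && all(dim(R) == c(3L, 3L)) &&
    max(abs(crossprod(R) - diag(3))) < tol && det(R) > 0
}

.atomColumns <- c("eleno", "elety", "resid", "resno", "chain",
                  "x", "y", "z", "element", "vdw", "sidechain", "copy")

.validAtomTable <- function(atoms) {
  missing <- setdiff(.atomColumns, names(atoms))
  if (length(missing))
    return(paste("atom table lacks columns:", paste(missing, collapse = ", ")))
  if (nrow(atoms)) {
    if (!all(is.finite(as.matrix(atoms[, c("x", "y", "z")]))))
      return("atom coordinates must be finite")
    if (!all(atoms$vdw > 0))
      return("van der Waals radii must be positive")
  }
  TRUE
}

#' Capsid structure: asymmetric-unit atoms plus assembly transforms
#'
#' Holds the deposited coordinates of one viral-protein (VP) asymmetric unit
#' together with the rigid-body transforms (REMARK 350 BIOMT or a supplied
#' transform file) that generate the biological assembly. Atom rows carry the
#' element-wise van der Waals radius and a side-chain flag (heavy atoms other
#' than N, CA, C, O, OXT); hydrogens are not expected in crystal structures
#' and are dropped on read.
#'
#' @slot atoms data.frame of atom records (`copy` is 0 for the deposited unit).
#' @slot transforms list of 3x4 matrices `[R | t]` in Angstrom; the first is
#'   the identity and every rotation block is proper orthonormal.
#' @slot source character label (file name or generator tag).
#' @exportClass CapsidStructure
setClass("CapsidStructure",
  representation(atoms = "data.frame", transforms = "list",
                 source = "character"))

setValidity("CapsidStructure", function(object) {
  msg <- .validAtomTable(object@atoms)
  if (!isTRUE(msg)) return(msg)
  tr <- object@transforms
  if (!length(tr)) return("transforms must be non-empty")
  for (i in seq_along(tr)) {
    m <- tr[[i]]
    if (!is.matrix(m) || !all(dim(m) == c(3L, 4L)))
      return(sprintf("transform %d is not a 3x4 matrix", i))
    if (!.isRigidRotation(m[, 1:3]))
      return(sprintf("transform %d has a non-orthonormal rotation block", i))
  }
  if (max(abs(tr[[1]] - .identity34())) > 1e-6)
    return("first transform must be the identity")
  TRUE
})

#' Expanded capsid assembly
#'
#' All symmetry copies of the asymmetric unit, obtained by applying each
#' transform of a [CapsidStructure-class]; `center` is the centroid of every
#' atom of the full particle, the origin for the outer-shell radial filter.
#'
#' @slot atoms data.frame with one row per transformed atom; `copy` indexes
#'   the generating transform (0-based, 0 = deposited orientation).
#' @slot center numeric(3) centroid of all assembly atoms, Angstrom.
#' @slot nCopies integer number of symmetry copies.
#' @exportClass CapsidAssembly
setClass("CapsidAssembly",
  representation(atoms = "data.frame", center = "numeric",
                 nCopies = "integer"))

setValidity("CapsidAssembly", function(object) {
  msg <- .validAtomTable(object@atoms)
  if (!isTRUE(msg)) return(msg)
  if (length(object@center) != 3L || !all(is.finite(object@center)))
    return("center must be a finite 3-vector")
  if (length(unique(object@atoms$copy)) != object@nCopies)
    return("number of distinct copies must equal nCopies")
  ctr <- colMeans(object@atoms[, c("x", "y", "z")])
  if (max(abs(ctr - object@center)) > 1e-9)
    return("center is not the centroid of the assembly atoms")
  TRUE
})

#' Outer-surface side-chain SASA of one VP, by residue category
#'
#' Per-serotype sums of side-chain solvent-accessible surface area over the
#' reference VP's atoms lying strictly farther than `radialThreshold` from
#' the capsid center, accumulated by residue category. The hydrophilic sum
#' is, by construction, the acidic plus the basic sum.
#'
#' @slot serotype character label.
#' @slot sasaHydrophobic,sasaAcidic,sasaBasic,sasaHydrophilic numeric sums
#'   in Angstrom^2.
#' @slot nAtomsOuter integer count of reference side-chain atoms beyond the
#'   radial threshold.
#' @slot radialThreshold,probeRadius numeric, Angstrom.
#' @exportClass OuterSASAResult
setClass("OuterSASAResult",
  representation(serotype = "character",
                 sasaHydrophobic = "numeric", sasaAcidic = "numeric",
                 sasaBasic = "numeric", sasaHydrophilic = "numeric",
                 nAtomsOuter = "integer",
                 radialThreshold = "numeric", probeRadius = "numeric"))

setValidity("OuterSASAResult", function(object) {
  s <- c(object@sasaHydrophobic, object@sasaAcidic, object@sasaBasic,
         object@sasaHydrophilic)
  if (any(s < 0)) return("SASA sums must be non-negative")
  if (object@sasaHydrophilic != object@sasaAcidic + object@sasaBasic)
    return("sasaHydrophilic must equal sasaAcidic + sasaBasic exactly")
  if (object@nAtomsOuter < 0L) return("nAtomsOuter must be >= 0")
  TRUE
})

#' Fitted adsorption regression model
#'
#' An ordinary-least-squares fit of the adsorption ratio (percent) on surface
#' and capsid descriptors, for one of the nested variants: `S1` (contact
#' angle + signed zeta), `S2` (adds the positive/negative zeta split) or
#' `final` (adds hydrophobic and hydrophilic outer SASA). Stores everything
#' needed to report the coefficient table, standardized coefficients and
#' predictions without refitting.
#'
#' @slot variant character, one of "S1", "S2", "final" (or "custom").
#' @slot encoding character zeta encoding used ("magnitude" or "signed").
#' @slot variables character predictor names (excluding the intercept).
#' @slot coefficients,standardErrors,tValues,pValues named numeric vectors,
#'   intercept first.
#' @slot rSquared numeric in [0, 1].
#' @slot n integer number of observations.
#' @slot standardizedCoefficients named numeric, z-score-scale slopes
#'   (intercept entry is 0 by construction).
#' @slot xMeans,xSds numeric per-predictor moments of the training design.
#' @slot yMean,ySd numeric response moments.
#' @slot fitted,residuals numeric vectors.
#' @exportClass AdsorptionFit
setClass("AdsorptionFit",
  representation(variant = "character", encoding = "character",
                 variables = "character",
                 coefficients = "numeric", standardErrors = "numeric",
                 tValues = "numeric", pValues = "numeric",
                 rSquared = "numeric", n = "integer",
                 standardizedCoefficients = "numeric",
                 xMeans = "numeric", xSds = "numeric",
                 yMean = "numeric", ySd = "numeric",
                 fitted = "numeric", residuals = "numeric"))

setValidity("AdsorptionFit", function(object) {
  k <- length(object@variables)
  if (length(object@coefficients) != k + 1L)
    return("coefficients must have one entry per variable plus intercept")
  lens <- c(length(object@standardErrors), length(object@tValues),
            length(object@pValues))
  if (any(lens != k + 1L))
    return("standardErrors/tValues/pValues lengths inconsistent")
  if (object@rSquared < -1e-12 || object@rSquared > 1 + 1e-12)
    return("rSquared must lie in [0, 1]")
  if (object@n <= k + 1L)
    return("fit requires more observations than parameters")
  TRUE
})

#' @describeIn CapsidStructure-class compact display
#' @param object a `CapsidStructure`
#' @export
setMethod("show", "CapsidStructure", function(object) {
  cat("CapsidStructure:", nrow(object@atoms), "atoms,",
      length(object@transforms), "assembly transforms",
      sprintf("[%s]\n", object@source))
})

#' @describeIn CapsidAssembly-class compact display
#' @param object a `CapsidAssembly`
#' @export
setMethod("show", "CapsidAssembly", function(object) {
  cat("CapsidAssembly:", object@nCopies, "copies,",
      nrow(object@atoms), "atoms; center",
      sprintf("(%.2f, %.2f, %.2f) A\n", object@center[1], object@center[2],
              object@center[3]))
})

#' @describeIn OuterSASAResult-class compact display
#' @param object an `OuterSASAResult`
#' @export
setMethod("show", "OuterSASAResult", function(object) {
  cat(sprintf(
    "OuterSASAResult '%s' (> %.0f A, probe %.1f A, %d outer atoms)\n",
    object@serotype, object@radialThreshold, object@probeRadius,
    object@nAtomsOuter))
  cat(sprintf("  hydrophobic %.1f  acidic %.1f  basic %.1f  hydrophilic %.1f A^2\n",
              object@sasaHydrophobic, object@sasaAcidic, object@sasaBasic,
              object@sasaHydrophilic))
})

#' @describeIn AdsorptionFit-class compact display
#' @param object an `AdsorptionFit`
#' @export
setMethod("show", "AdsorptionFit", function(object) {
  cat(sprintf("AdsorptionFit variant '%s' (zeta encoding: %s), n = %d\n",
              object@variant, object@encoding, object@n))
  print(coefTable(object), digits = 4)
  cat(sprintf("R-squared: %.4f\n", object@rSquared))
})
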