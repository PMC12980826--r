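# Outer-shell side-chain SASA sums by residue category, and the high-level
# per-serotype descriptor computation.

#' Sum outer-surface side-chain SASA by residue category
#'
#' Given per-atom SASA computed on a VP neighborhood (so inter-subunit
#' burial is already reflected), sums the SASA of the reference copy's
#' side-chain atoms lying strictly farther than `radialThreshold` from the
#' capsid center, accumulated into the atom's residue category. Unclassified
#' residues contribute to no category; the hydrophilic sum is acidic +
#' basic.
#'
#' @param neighborhood atom data.frame from [selectNeighborhood()] (carries
#'   a `referenceCopy` attribute, or pass `referenceCopy` explicitly)
#' @param center numeric(3) capsid center (centroid of the full assembly),
#'   Angstrom
#' @param perAtomSasa numeric SASA per neighborhood atom, Angstrom^2
#' @param radialThreshold numeric, Angstrom (> 0); atoms at exactly the
#'   threshold are excluded (strictly "more than")
#' @param referenceCopy integer, defaults to the attribute set by
#'   [selectNeighborhood()]
#' @param serotype label stored in the result
#' @param probeRadius probe radius recorded in the result, Angstrom
#' @return an [OuterSASAResult-class]
#' @export
outerSidechainSasa <- function(neighborhood, center, perAtomSasa,
                               radialThreshold = 105,
                               referenceCopy = attr(neighborhood,
                                                    "referenceCopy"),
                               serotype = "", probeRadius = 1.4) {
  stopifnot(radialThreshold > 0, length(center) == 3L,
            nrow(neighborhood) == length(perAtomSasa))
  if (is.null(referenceCopy))
    stop("referenceCopy not given and not carried by the neighborhood")
  d <- sqrt((neighborhood$x - center[1])^2 +
            (neighborhood$y - center[2])^2 +
            (neighborhood$z - center[3])^2)
  sel <- neighborhood$copy == referenceCopy & neighborhood$sidechain &
         d > radialThreshold
  if (!any(sel))
    warning("no reference side-chain atom beyond ", radialThreshold,
            " A; all outer SASA sums are 0")
  cat3 <- classifyResidue(neighborhood$resid[sel])
  s <- perAtomSasa[sel]
  sums <- vapply(c("hydrophobic", "acidic", "basic"),
                 function(k) sum(s[cat3 == k]), numeric(1))
  methods::new("OuterSASAResult", serotype = as.character(serotype),
               sasaHydrophobic = sums[["hydrophobic"]],
               sasaAcidic = sums[["acidic"]],
               sasaBasic = sums[["basic"]],
               sasaHydrophilic = sums[["acidic"]] + sums[["basic"]],
               nAtomsOuter = sum(sel),
               radialThreshold = radialThreshold,
               probeRadius = probeRadius)
}

#' Per-serotype capsid surface descriptor
#'
#' End-to-end computation for one serotype: expand the biological assembly,
#' select the reference VP plus contacting neighbors, run Shrake-Rupley
#' SASA on that neighborhood, and sum outer-shell side-chain SASA by
#' residue category.
#'
#' @param structure a [CapsidStructure-class]
#' @param serotype label
#' @param radialThreshold outer-shell radius cut, Angstrom (default 105,
#'   set for ~26-nm AAV capsids)
#' @param probeRadius water-probe radius, Angstrom
#' @param nPoints Shrake-Rupley quadrature points per atom
#' @param contactCutoff neighbor contact distance, Angstrom
#' @param referenceCopy which assembly copy is the VP of interest
#' @return an [OuterSASAResult-class]
#' @export
capsidDescriptor <- function(structure, serotype = structure@source,
                             radialThreshold = 105, probeRadius = 1.4,
                             nPoints = 960L, contactCutoff = 6,
                             referenceCopy = 0L) {
  assembly <- expandAssembly(structure)
  hood <- selectNeighborhood(assembly, referenceCopy = referenceCopy,
                             contactCutoff = contactCutoff)
  sasa <- shrakeRupleySasa(as.matrix(hood[, c("x", "y", "z")]), hood$vdw,
                           probeRadius = probeRadius, nPoints = nPoints)
  outerSidechainSasa(hood, center = assembly@center, perAtomSasa = sasa,
                     radialThreshold = radialThreshold,
                     serotype = serotype, probeRadius = probeRadius)
}

#' Pearson correlation between acidic and basic outer SASA
#'
#' Across serotypes, acidic and basic outer SASA are typically strongly
#' correlated; when the correlation magnitude exceeds a threshold the two
#' are merged into the single hydrophilic explanatory variable used by the
#' adsorption model.
#'
#' @param descriptors list of [OuterSASAResult-class] (>= 3) or a
#'   data.frame with columns `sasa_acidic`, `sasa_basic`
#' @return Pearson r
#' @export
acidicBasicCorrelation <- function(descriptors) {
  if (is.data.frame(descriptors)) {
    a <- descriptors$sasa_acidic
    b <- descriptors$sasa_basic
  } else {
    a <- vapply(descriptors, function(d) d@sasaAcidic, numeric(1))
    b <- vapply(descriptors, function(d) d@sasaBasic, numeric(1))
  }
  if (length(a) < 3L) stop("need at least 3 serotype descriptors")
  if (stats::sd(a) == 0 || stats::sd(b) == 0)
    stop("acidic/basic SASA correlation undefined: zero variance")
  stats::cor(a, b)
}

#' Assemble a descriptor table from per-serotype results
#' @param descriptors list of [OuterSASAResult-class]
#' @return data.frame with one row per serotype
#' @export
descriptorTable <- function(descriptors) {
  do.call(rbind, lapply(descriptors, function(d) data.frame(
    serotype = d@serotype,
    sasa_hydrophobic = d@sasaHydrophobic,
    sasa_acidic = d@sasaAcidic,
    sasa_basic = d@sasaBasic,
    sasa_hydrophilic = d@sasaHydrophilic,
    n_atoms_outer = d@nAtomsOuter,
    stringsAsFactors = FALSE)))
}
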