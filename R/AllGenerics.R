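#' Expand a structure into its biological assembly
#'
#' Applies every rigid-body transform of a [CapsidStructure-class] to its
#' atoms, producing the full particle (for an icosahedral capsid, 60 copies
#' of the VP asymmetric unit). The assembly centroid becomes the reference
#' origin for the outer-shell radial filter.
#'
#' @param object a [CapsidStructure-class]
#' @return a [CapsidAssembly-class]
#' @examples
#' toy <- generateToyCapsid(nCopies = 4, atomsPerCopy = 3, seed = 1)
#' expandAssembly(toy$structure)
#' @export
setGeneric("expandAssembly", function(object) standardGeneric("expandAssembly"))

#' Select one VP and its contacting neighbor copies
#'
#' Returns the reference copy plus every assembly copy having at least one
#' atom within `contactCutoff` Angstrom of any reference atom. This is the
#' "single VP surrounded by neighboring VPs" context in which SASA is
#' evaluated, so that inter-subunit burial is accounted for.
#'
#' @param object a [CapsidAssembly-class]
#' @param referenceCopy integer copy index (0 = deposited orientation)
#' @param contactCutoff numeric heavy-atom contact distance, Angstrom (> 0)
#' @return data.frame of atoms (reference + neighbors) with attribute
#'   `referenceCopy`; warns when no neighbor qualifies.
#' @export
setGeneric("selectNeighborhood",
  function(object, referenceCopy = 0L, contactCutoff = 6)
    standardGeneric("selectNeighborhood"))

#' Coefficient table of a fitted adsorption model
#'
#' @param object an [AdsorptionFit-class]
#' @return data.frame with columns variable, coefficient, std_error,
#'   t_value, p_value (intercept first).
#' @export
setGeneric("coefTable", function(object) standardGeneric("coefTable"))

#' Coefficient of determination of a fitted adsorption model
#' @param object an [AdsorptionFit-class]
#' @return numeric R-squared in [0, 1]
#' @export
setGeneric("rSquared", function(object) standardGeneric("rSquared"))

#' Standardized (z-score scale) regression coefficients
#'
#' Slopes after z-scoring every predictor and the response; comparable
#' across variables with different units. Computed by the exact rescaling
#' identity `beta_std = beta * sd(x) / sd(y)`.
#'
#' @param object an [AdsorptionFit-class]
#' @return named numeric vector (no intercept entry)
#' @export
setGeneric("standardizedCoefficients",
  function(object) standardGeneric("standardizedCoefficients"))
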