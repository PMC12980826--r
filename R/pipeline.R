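# End-to-end driver: descriptors -> feature build -> nested fits ->
# standardized coefficients -> optional predictions, with a JSON run
# manifest recording every default actually used.

#' Run the adsorption-modelling pipeline
#'
#' Reproducible end-to-end workflow. Capsid descriptors are either taken
#' from `descriptors` (a data.frame or CSV path) or computed from
#' `structures` (named list of [CapsidStructure-class] or PDB paths) with
#' the SASA engine. Acidic and basic outer SASA are reported separately
#' with their cross-serotype Pearson correlation and merged into the
#' single hydrophilic variable when the correlation magnitude reaches
#' `mergeThreshold` (they are merged either way, with a message when the
#' correlation is weak, since the final model is defined on the merged
#' variable). The requested model variants are then fitted in their
#' nested order and, when `newConditions` is given, the final variant
#' predicts adsorption under those conditions.
#'
#' @param conditions condition table (data.frame or CSV path; see
#'   [readConditionTable()])
#' @param descriptors per-serotype descriptor table (data.frame or CSV
#'   path), or NULL to compute from `structures`
#' @param structures named list (serotype -> [CapsidStructure-class] or
#'   PDB path), used when `descriptors` is NULL
#' @param variants character subset of `c("S1", "S2", "final")`
#' @param encoding zeta encoding for [splitZeta()]
#' @param mergeThreshold |r| above which acidic/basic merging is reported
#'   as justified
#' @param newConditions optional condition table for prediction (response
#'   column not required)
#' @param outDir optional output directory; when given, every stage table
#'   plus `manifest.json` is written there
#' @param radialThreshold,probeRadius,nPoints,contactCutoff SASA engine
#'   parameters (used only when descriptors are computed from structures)
#' @return list with `descriptors`, `acidicBasicR` (NA when fewer than 3
#'   serotypes or descriptors lack the split), `fits` (named list of
#'   [AdsorptionFit-class]), `rSquared` (named vector in variant order),
#'   `standardized` (final-variant standardized coefficients),
#'   `predictions` (or NULL), `manifest`
#' @export
runPipeline <- function(conditions, descriptors = NULL, structures = NULL,
                        variants = c("S1", "S2", "final"),
                        encoding = c("magnitude", "signed"),
                        mergeThreshold = 0.9,
                        newConditions = NULL, outDir = NULL,
                        radialThreshold = 105, probeRadius = 1.4,
                        nPoints = 960L, contactCutoff = 6) {
  encoding <- match.arg(encoding)
  variants <- match.arg(variants, several.ok = TRUE)
  inputFiles <- character(0)

  if (is.character(conditions)) {
    inputFiles <- c(inputFiles, conditions)
    conditions <- readConditionTable(conditions)
  }
  if (is.null(descriptors)) {
    if (is.null(structures))
      stop("stage 'descriptors': supply a descriptor table or structures")
    descs <- lapply(names(structures), function(nm) {
      s <- structures[[nm]]
      if (is.character(s)) {
        inputFiles <<- c(inputFiles, s)
        s <- readCapsidStructure(s)
      }
      capsidDescriptor(s, serotype = nm, radialThreshold = radialThreshold,
                       probeRadius = probeRadius, nPoints = nPoints,
                       contactCutoff = contactCutoff)
    })
    descriptors <- descriptorTable(descs)
  } else if (is.character(descriptors)) {
    inputFiles <- c(inputFiles, descriptors)
    descriptors <- readDescriptorTable(descriptors)
  }

  acidicBasicR <- NA_real_
  if (!is.null(descriptors$sasa_acidic) &&
      !is.null(descriptors$sasa_basic) && nrow(descriptors) >= 3L) {
    acidicBasicR <- acidicBasicCorrelation(descriptors)
    if (abs(acidicBasicR) < mergeThreshold)
      message("acidic/basic SASA correlation |r| = ",
              signif(abs(acidicBasicR), 3), " is below the merge ",
              "threshold ", mergeThreshold,
              "; they are still combined into the hydrophilic variable ",
              "the final model is defined on")
  }

  fits <- list()
  for (v in c("S1", "S2", "final")[c("S1", "S2", "final") %in% variants]) {
    design <- tryCatch(
      buildDesign(conditions, descriptors, variant = v,
                  encoding = encoding),
      error = function(e) stop("stage 'design' (variant ", v, "): ",
                               conditionMessage(e), call. = FALSE))
    fits[[v]] <- tryCatch(
      fitAdsorptionModel(design),
      error = function(e) stop("stage 'fit' (variant ", v, "): ",
                               conditionMessage(e), call. = FALSE))
  }
  r2 <- vapply(fits, rSquared, numeric(1))

  predictions <- NULL
  if (!is.null(newConditions)) {
    if (is.character(newConditions)) {
      inputFiles <- c(inputFiles, newConditions)
      newConditions <- utils::read.csv(newConditions,
                                       stringsAsFactors = FALSE)
    }
    fitFinal <- fits[[length(fits)]]
    nd <- newConditions
    if (!is.null(nd$response_percent)) nd$response_percent <- NULL
    nd$response_percent <- 0   # buildDesign requires the column
    ndesign <- buildDesign(nd, descriptors,
                           variant = fitFinal@variant, encoding = encoding)
    predictions <- cbind(
      newConditions[, intersect(c("serotype", "surface_id", "buffer_id"),
                                names(newConditions)), drop = FALSE],
      predict(fitFinal, as.data.frame(ndesign$X)))
  }

  config <- list(variants = variants, encoding = encoding,
                 mergeThreshold = mergeThreshold,
                 radialThreshold = radialThreshold,
                 probeRadius = probeRadius, nPoints = nPoints,
                 contactCutoff = contactCutoff)
  manifest <- list(
    package = "CapsidAdsorb",
    version = as.character(utils::packageVersion("CapsidAdsorb")),
    config = config,
    configHash = .hashObject(config),
    inputChecksums = as.list(.fileChecksums(inputFiles)),
    nConditions = nrow(conditions),
    acidicBasicR = acidicBasicR,
    rSquared = as.list(r2))

  result <- list(descriptors = descriptors, acidicBasicR = acidicBasicR,
                 fits = fits, rSquared = r2,
                 standardized =
                   standardizedCoefficients(fits[[length(fits)]]),
                 predictions = predictions, manifest = manifest)

  if (!is.null(outDir)) {
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    writeTable(descriptors, file.path(outDir, "descriptors.csv"))
    for (v in names(fits))
      writeTable(coefTable(fits[[v]]),
                 file.path(outDir, paste0("coefficients_", v, ".csv")))
    writeTable(data.frame(variable = names(result$standardized),
                          standardized_coefficient =
                            unname(result$standardized)),
               file.path(outDir, "standardized_coefficients.csv"))
    if (!is.null(predictions))
      writeTable(predictions, file.path(outDir, "predictions.csv"))
    jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  result
}

.hashObject <- function(x) {
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA), f)
  unname(tools::md5sum(f))
}

.fileChecksums <- function(files) {
  files <- unique(files[file.exists(files)])
  if (!length(files)) return(stats::setNames(character(0), character(0)))
  stats::setNames(unname(tools::md5sum(files)), basename(files))
}
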