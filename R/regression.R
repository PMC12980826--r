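# Sign-split feature construction and nested OLS adsorption models.
#
# The final model is
#   A = b0 + b1*theta + b2*zeta_pos + b3*zeta_neg
#          + b4*S_hydrophobic + b5*S_hydrophilic
# with A the adsorption ratio (%), theta the surface contact angle (deg),
# zeta split into its positive and negative components (mV), and the S
# terms the capsid outer side-chain SASA sums (A^2). Variant S1 uses
# {theta, zeta}; S2 adds the sign split; `final` adds the SASA terms.

.variantColumns <- list(
  S1 = c("theta_deg", "zeta_mV"),
  S2 = c("theta_deg", "zeta_pos_mV", "zeta_neg_mV"),
  final = c("theta_deg", "zeta_pos_mV", "zeta_neg_mV",
            "sasa_hydrophobic", "sasa_hydrophilic"))

#' Split a signed zeta potential into positive and negative components
#'
#' Negatively charged rAAV particles adsorb onto positively charged
#' surfaces by global attraction but also onto negatively charged surfaces
#' through localized positive patches; giving each sign its own regressor
#' lets the model carry both effects. Under the default `magnitude`
#' encoding both components are non-negative (`zeta_neg` is the absolute
#' value of a negative zeta); under `signed` the negative component keeps
#' its sign. At most one component is nonzero and
#' `zeta_pos - zeta_neg` (magnitude) reconstructs the signed value.
#'
#' @param zeta numeric zeta potential(s), mV
#' @param encoding "magnitude" (default) or "signed"
#' @return data.frame with columns `zeta_pos_mV`, `zeta_neg_mV`
#' @examples
#' splitZeta(c(37.2, -61.7, 0))
#' @export
splitZeta <- function(zeta, encoding = c("magnitude", "signed")) {
  encoding <- match.arg(encoding)
  stopifnot(all(is.finite(zeta)))
  pos <- pmax(zeta, 0)
  neg <- if (encoding == "magnitude") pmax(-zeta, 0) else pmin(zeta, 0)
  data.frame(zeta_pos_mV = pos, zeta_neg_mV = neg)
}

#' Build the regression design for a model variant
#'
#' Joins condition rows (surface x buffer x serotype, with measured
#' contact angle, zeta and mean adsorption ratio) to per-serotype capsid
#' descriptors and assembles the predictor matrix for the requested
#' variant. The intercept is added at fit time.
#'
#' @param conditions data.frame with columns `serotype`, `surface_id`,
#'   `buffer_id`, `theta_deg`, `zeta_mV`, `response_percent`
#' @param descriptors data.frame with columns `serotype`,
#'   `sasa_hydrophobic`, `sasa_hydrophilic` (required for the `final`
#'   variant; see [descriptorTable()])
#' @param variant "S1", "S2" or "final"
#' @param encoding zeta encoding passed to [splitZeta()]
#' @return list with `X` (numeric matrix, no intercept column), `y`
#'   (response, percent), `variant`, `encoding`
#' @export
buildDesign <- function(conditions, descriptors = NULL,
                        variant = c("final", "S1", "S2"),
                        encoding = c("magnitude", "signed")) {
  variant <- match.arg(variant)
  encoding <- match.arg(encoding)
  need <- c("serotype", "surface_id", "buffer_id", "theta_deg", "zeta_mV",
            "response_percent")
  miss <- setdiff(need, names(conditions))
  if (length(miss))
    stop("conditions table lacks columns: ", paste(miss, collapse = ", "))
  key <- paste(conditions$serotype, conditions$surface_id,
               conditions$buffer_id, sep = "|")
  if (anyDuplicated(key))
    stop("duplicate condition key(s): ",
         paste(unique(key[duplicated(key)]), collapse = "; "))

  df <- data.frame(theta_deg = conditions$theta_deg,
                   zeta_mV = conditions$zeta_mV)
  df <- cbind(df, splitZeta(conditions$zeta_mV, encoding))

  if (variant == "final") {
    if (is.null(descriptors))
      stop("the 'final' variant needs a serotype descriptor table")
    if (anyDuplicated(descriptors$serotype))
      stop("duplicate serotype key(s) in descriptors: ",
           paste(unique(descriptors$serotype[
             duplicated(descriptors$serotype)]), collapse = ", "))
    idx <- match(conditions$serotype, descriptors$serotype)
    if (anyNA(idx))
      stop("no descriptor for serotype(s): ",
           paste(unique(conditions$serotype[is.na(idx)]), collapse = ", "))
    df$sasa_hydrophobic <- descriptors$sasa_hydrophobic[idx]
    df$sasa_hydrophilic <- descriptors$sasa_hydrophilic[idx]
  }
  X <- as.matrix(df[, .variantColumns[[variant]], drop = FALSE])
  list(X = X, y = as.numeric(conditions$response_percent),
       variant = variant, encoding = encoding)
}

#' Fit an ordinary-least-squares adsorption model
#'
#' Fits `y ~ X` with an intercept via `stats::lm`, after checking the
#' design for (near-)collinear columns. Reports coefficients, standard
#' errors, t-values (df = n - k - 1), two-sided p-values, R-squared and
#' the standardized coefficients `beta_std = beta * sd(x) / sd(y)`. A
#' constant response is a valid degenerate fit with all slopes 0 and
#' R-squared 0.
#'
#' @param design list from [buildDesign()], or pass `X` and `y` directly
#' @param X,y alternative direct inputs (predictor matrix without
#'   intercept; response vector)
#' @param variant,encoding labels stored in the fit (taken from `design`
#'   when given)
#' @return an [AdsorptionFit-class]
#' @export
fitAdsorptionModel <- function(design = NULL, X = design$X, y = design$y,
                               variant = if (!is.null(design))
                                 design$variant else "custom",
                               encoding = if (!is.null(design))
                                 design$encoding else "magnitude") {
  X <- as.matrix(X)
  if (is.null(colnames(X)))
    colnames(X) <- paste0("x", seq_len(ncol(X)))
  n <- nrow(X); k <- ncol(X)
  if (n <= k + 1L)
    stop("need more observations (", n, ") than parameters (", k + 1L, ")")
  Xi <- cbind(`(Intercept)` = 1, X)
  qrX <- qr(Xi, tol = 1e-10)
  if (qrX$rank < ncol(Xi)) {
    dep <- colnames(Xi)[qrX$pivot[(qrX$rank + 1L):ncol(Xi)]]
    stop("singular design: column(s) ", paste(dep, collapse = ", "),
         " are collinear with the others")
  }

  fit <- stats::lm(y ~ ., data = data.frame(y = y, X, check.names = FALSE))
  # a noiseless (perfect) fit is a legitimate degenerate case here
  sm <- withCallingHandlers(summary(fit),
    warning = function(w) {
      if (grepl("essentially perfect fit", conditionMessage(w)))
        invokeRestart("muffleWarning")
    })
  ct <- sm$coefficients
  coefs <- ct[, "Estimate"]
  se <- ct[, "Std. Error"]
  tv <- ct[, "t value"]
  pv <- ct[, "Pr(>|t|)"]
  sdY <- stats::sd(y)
  if (sdY == 0) { tv[] <- 0; pv[] <- NA_real_ }
  r2 <- if (sdY == 0) 0 else sm$r.squared

  sdX <- apply(X, 2, stats::sd)
  std <- c(0, if (sdY == 0) rep(0, k) else coefs[-1] * sdX / sdY)
  names(std) <- names(coefs)

  methods::new("AdsorptionFit",
    variant = variant, encoding = encoding, variables = colnames(X),
    coefficients = coefs, standardErrors = se, tValues = tv, pValues = pv,
    rSquared = max(0, min(1, r2)), n = as.integer(n),
    standardizedCoefficients = std,
    xMeans = colMeans(X), xSds = sdX, yMean = mean(y), ySd = sdY,
    fitted = unname(stats::fitted(fit)),
    residuals = unname(stats::residuals(fit)))
}

#' Refit on z-scored variables
#'
#' Standardizes every predictor column and the response and refits; the
#' slope estimates equal `beta * sd(x) / sd(y)` of the raw fit up to
#' floating-point error, which the test suite asserts.
#'
#' @param X predictor matrix (no intercept), every column with nonzero
#'   variance
#' @param y response vector with nonzero variance
#' @return an [AdsorptionFit-class] on the z-score scale
#' @export
standardizedFit <- function(X, y) {
  X <- as.matrix(X)
  sdX <- apply(X, 2, stats::sd)
  if (any(sdX == 0))
    stop("zero-variance column(s): ",
         paste(colnames(X)[sdX == 0], collapse = ", "))
  if (stats::sd(y) == 0) stop("zero-variance response")
  fitAdsorptionModel(X = scale(X), y = as.numeric(scale(y)),
                     variant = "standardized")
}

#' @rdname coefTable
#' @export
setMethod("coefTable", "AdsorptionFit", function(object) {
  data.frame(variable = names(object@coefficients),
             coefficient = unname(object@coefficients),
             std_error = unname(object@standardErrors),
             t_value = unname(object@tValues),
             p_value = unname(object@pValues),
             stringsAsFactors = FALSE)
})

#' @rdname rSquared
#' @export
setMethod("rSquared", "AdsorptionFit", function(object) object@rSquared)

#' @rdname standardizedCoefficients
#' @export
setMethod("standardizedCoefficients", "AdsorptionFit", function(object)
  object@standardizedCoefficients[-1])

#' Predict adsorption ratios under new conditions
#'
#' Linear prediction from a fitted model; reported both raw and clamped to
#' the physically observable `[0, 100]` percent window (the assay cannot
#' report a loss outside it).
#'
#' @param object an [AdsorptionFit-class]
#' @param newdata data.frame or matrix carrying every fitted variable as a
#'   column
#' @return data.frame with columns `raw_percent`, `clamped_percent`
#' @export
setMethod("predict", "AdsorptionFit", function(object, newdata) {
  newdata <- as.data.frame(newdata)
  miss <- setdiff(object@variables, names(newdata))
  if (length(miss))
    stop("newdata lacks fitted variable(s): ", paste(miss, collapse = ", "))
  Xn <- as.matrix(newdata[, object@variables, drop = FALSE])
  raw <- drop(cbind(1, Xn) %*% object@coefficients)
  data.frame(raw_percent = raw,
             clamped_percent = pmin(100, pmax(0, raw)))
})

#' Validation R-squared between observed and predicted values
#'
#' Two common definitions: the squared Pearson correlation of observed vs
#' predicted (default), and `1 - SS_res / SS_tot` about the observed mean
#' (which can be negative for a poor predictor). Both are provided because
#' published "measured vs predicted" R-squared values rarely say which was
#' used.
#'
#' @param observed,predicted equal-length numeric vectors (n >= 3)
#' @param definition "pearson_squared" or "one_minus_ssres"
#' @return numeric R-squared
#' @export
validationR2 <- function(observed, predicted,
                         definition = c("pearson_squared",
                                        "one_minus_ssres")) {
  definition <- match.arg(definition)
  if (length(observed) != length(predicted))
    stop("observed and predicted must have equal length")
  if (length(observed) < 3L) stop("need at least 3 pairs")
  if (stats::sd(observed) == 0)
    stop("zero variance in observed values")
  if (definition == "pearson_squared") {
    if (stats::sd(predicted) == 0)
      stop("pearson_squared undefined for a constant predictor")
    stats::cor(observed, predicted)^2
  } else {
    1 - sum((observed - predicted)^2) / sum((observed - mean(observed))^2)
  }
}
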