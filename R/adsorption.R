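# Adsorption-ratio assay statistics: the clamped titer-loss ratio,
# replicate summaries, and the two-tailed unpaired (pooled-variance)
# Student's t-test with significance stars.

#' Adsorption ratio from genomic titers
#'
#' `100 * (before - after) / before`, the percent loss of genomic titer
#' after incubation with a surface. A negative ratio is treated as a
#' measurement error and clamped to 0%; the result always lies in
#' `[0, 100]` for valid titers. The clamp is applied per replicate ratio,
#' before any averaging.
#'
#' @param titerBefore titer before adsorption, vg/mL (> 0); vectorized
#' @param titerAfter titer after adsorption, vg/mL (>= 0); vectorized
#' @return adsorption ratio(s) in percent
#' @examples
#' adsorptionRatio(5.5e10, 2.75e10)   # 50
#' adsorptionRatio(1.0e10, 1.1e10)    # 0 (clamped)
#' @export
adsorptionRatio <- function(titerBefore, titerAfter) {
  if (any(titerBefore <= 0)) stop("titerBefore must be > 0")
  if (any(titerAfter < 0)) stop("titerAfter must be >= 0")
  pmax(0, 100 * (titerBefore - titerAfter) / titerBefore)
}

#' Summarise replicate adsorption ratios
#'
#' Arithmetic mean and sample standard deviation (n - 1 denominator); a
#' single replicate reports sd = 0.
#'
#' @param ratios numeric vector of percent ratios (non-empty)
#' @return data.frame with columns `mean`, `sd`, `n`
#' @export
summarizeReplicates <- function(ratios) {
  if (!length(ratios)) stop("no replicate ratios supplied")
  n <- length(ratios)
  data.frame(mean = mean(ratios),
             sd = if (n == 1L) 0 else stats::sd(ratios),
             n = n)
}

#' Two-tailed unpaired Student's t-test with significance stars
#'
#' Pooled-variance two-sample t-test (not Welch's), two-sided, with the
#' conventional star coding: `*` p < 0.05, `**` p < 0.01, `***` p < 0.001.
#' Two identical constant groups are reported as t = 0, p = 1.
#'
#' @param groupA,groupB numeric vectors (>= 2 values each)
#' @return list with `t`, `p`, `stars`, `df`
#' @export
studentTTest <- function(groupA, groupB) {
  if (length(groupA) < 2L || length(groupB) < 2L)
    stop("each group needs at least 2 values")
  if (stats::sd(groupA) == 0 && stats::sd(groupB) == 0 &&
      mean(groupA) == mean(groupB)) {
    return(list(t = 0, p = 1, stars = "",
                df = length(groupA) + length(groupB) - 2L))
  }
  tt <- stats::t.test(groupA, groupB, var.equal = TRUE,
                      alternative = "two.sided")
  list(t = unname(tt$statistic), p = tt$p.value,
       stars = significanceStars(tt$p.value),
       df = unname(tt$parameter))
}

#' Significance stars for a p-value
#' @param p numeric p-value(s)
#' @return character: `***` (p < 0.001), `**` (p < 0.01), `*` (p < 0.05),
#'   or `""`
#' @export
significanceStars <- function(p) {
  as.character(cut(p, breaks = c(-Inf, 0.001, 0.01, 0.05, Inf),
                   labels = c("***", "**", "*", ""), right = FALSE))
}

#' Summarise an adsorption observation table
#'
#' Computes the clamped adsorption ratio per replicate (unless a
#' `ratio_percent` column is already present) and the per-condition mean,
#' sd, n over serotype x surface x buffer groups.
#'
#' @param observations data.frame with columns `serotype`, `surface_id`,
#'   `buffer_id`, `replicate`, and either `titer_before_vg_ml` +
#'   `titer_after_vg_ml` or `ratio_percent`
#' @return tidy data.frame: one row per condition with `mean_percent`,
#'   `sd_percent`, `n`
#' @export
summarizeAdsorption <- function(observations) {
  obs <- observations
  if (is.null(obs$ratio_percent)) {
    if (is.null(obs$titer_before_vg_ml) || is.null(obs$titer_after_vg_ml))
      stop("observations need ratio_percent or titer columns")
    obs$ratio_percent <- adsorptionRatio(obs$titer_before_vg_ml,
                                         obs$titer_after_vg_ml)
  }
  key <- interaction(obs$serotype, obs$surface_id, obs$buffer_id,
                     drop = TRUE, lex.order = TRUE)
  parts <- lapply(split(obs, key), function(g) {
    s <- summarizeReplicates(g$ratio_percent)
    data.frame(serotype = g$serotype[1], surface_id = g$surface_id[1],
               buffer_id = g$buffer_id[1], mean_percent = s$mean,
               sd_percent = s$sd, n = s$n, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, parts)
  rownames(out) <- NULL
  out
}
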