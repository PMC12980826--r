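# Delimited-text I/O. All tables are comma-separated, UTF-8, one header
# row, with units embedded in the column names (theta_deg, zeta_mV,
# titer_before_vg_ml, ...) so unit errors fail loudly at validation.

.readCsv <- function(file, required) {
  df <- utils::read.csv(file, stringsAsFactors = FALSE,
                        fileEncoding = "UTF-8")
  miss <- setdiff(required, names(df))
  if (length(miss))
    stop(basename(file), " lacks column(s): ", paste(miss, collapse = ", "))
  df
}

.writeCsv <- function(df, file) {
  utils::write.csv(df, file, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(file)
}

#' Read a surface-condition table
#'
#' Columns: `surface_id`, `buffer_id`, `contact_angle_deg` (in
#' `[0, 180]`), `zeta_mV`.
#' @param file path to CSV
#' @return data.frame
#' @export
readSurfaceConditions <- function(file) {
  df <- .readCsv(file, c("surface_id", "buffer_id", "contact_angle_deg",
                         "zeta_mV"))
  if (any(df$contact_angle_deg < 0 | df$contact_angle_deg > 180))
    stop("contact angles must lie in [0, 180] degrees")
  df
}

#' Read a regression condition table
#'
#' Columns: `serotype`, `surface_id`, `buffer_id`, `theta_deg`, `zeta_mV`,
#' `response_percent`; the input [buildDesign()] consumes.
#' @param file path to CSV
#' @return data.frame
#' @export
readConditionTable <- function(file) {
  .readCsv(file, c("serotype", "surface_id", "buffer_id", "theta_deg",
                   "zeta_mV", "response_percent"))
}

#' Read a per-serotype SASA descriptor table
#' @param file path to CSV with columns `serotype`, `sasa_hydrophobic`,
#'   `sasa_hydrophilic` (and usually `sasa_acidic`, `sasa_basic`)
#' @return data.frame
#' @export
readDescriptorTable <- function(file) {
  .readCsv(file, c("serotype", "sasa_hydrophobic", "sasa_hydrophilic"))
}

#' Read an adsorption observation table
#' @param file path to CSV with columns `serotype`, `surface_id`,
#'   `buffer_id`, `replicate`, and titer or ratio columns (see
#'   [summarizeAdsorption()])
#' @return data.frame
#' @export
readAdsorptionObservations <- function(file) {
  .readCsv(file, c("serotype", "surface_id", "buffer_id", "replicate"))
}

#' Write a data.frame as a CSV table
#' @param df data.frame
#' @param file output path
#' @export
writeTable <- function(df, file) .writeCsv(df, file)
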