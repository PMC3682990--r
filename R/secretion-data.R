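#' Published glucose / insulin-secretion-rate table
#'
#' Seven (glucose, secretion rate) pairs assembled from in vivo human
#' measurements (overnight fast, mixed diet, hyperglycemic clamp) plus
#' three estimated anchor points added to constrain the fit at the low and
#' saturating ends. Shipped as a plain-text fixture under `extdata`.
#'
#' @return A tibble with columns `glucose_mM`, `rate_pM_per_min`,
#'   `provenance`.
#' @export
#' @examples
#' secretion_table()
secretion_table <- function() {
  read_secretion_csv(system.file("extdata", "secretion_rates.csv",
                                 package = "isletins", mustWork = TRUE))
}

#' Read or write a secretion dataset as CSV
#'
#' The interchange format is a CSV with header columns `glucose_mM`,
#' `rate_pM_per_min` and (optionally) `provenance`.
#'
#' @param path File path.
#' @return `read_secretion_csv()` returns a validated tibble;
#'   `write_secretion_csv()` returns `path` invisibly.
#' @export
read_secretion_csv <- function(path) {
  data <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!"provenance" %in% names(data)) data$provenance <- NA_character_
  check_secretion_data(data, min_points = 1L)
  tibble::as_tibble(data)
}

#' @rdname read_secretion_csv
#' @param data Data frame with the columns above.
#' @export
write_secretion_csv <- function(data, path) {
  check_secretion_data(data, min_points = 1L)
  utils::write.csv(data, path, row.names = FALSE)
  invisible(path)
}

#' Observed peripheral-insulin dose response used for validation
#'
#' Measured peripheral insulin concentrations at clamped glucose of 5, 7
#' and 16.5 mM, against which the model's equilibrium predictions are
#' compared by [validate_peripheral()].
#'
#' @return A tibble with columns `glucose_mM`, `insulin_pM`.
#' @export
observed_dose_response <- function() {
  tibble::as_tibble(utils::read.csv(
    system.file("extdata", "observed_dose_response.csv",
                package = "isletins", mustWork = TRUE)))
}
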