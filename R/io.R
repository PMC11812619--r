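#' Write a BMP dataset to tidy CSV files
#'
#' Writes the readings (`day, bottle_id, condition, cum_biogas_ml,
#' cum_ch4_ml, ch4_frac`) and the bottle metadata next to each other.
#'
#' @param ds A [bmp_dataset()].
#' @param path Readings CSV path; metadata goes to `<path base>_bottles.csv`.
#' @return Invisibly, the two paths written.
#' @export
write_bmp_csv <- function(ds, path) {
  stopifnot(inherits(ds, "bmp_dataset"))
  utils::write.csv(as.data.frame(ds), path, row.names = FALSE)
  bpath <- sub("\\.csv$", "_bottles.csv", path)
  utils::write.csv(attr(ds, "bottles"), bpath, row.names = FALSE)
  invisible(c(path, bpath))
}

#' Read a BMP dataset written by [write_bmp_csv()]
#'
#' @param path Readings CSV path (metadata expected at
#'   `<path base>_bottles.csv`).
#' @return A [bmp_dataset()].
#' @export
read_bmp_csv <- function(path) {
  readings <- utils::read.csv(path)
  bottles <- utils::read.csv(sub("\\.csv$", "_bottles.csv", path))
  bmp_dataset(readings, bottles)
}

#' Read or write a fermenter monitoring series
#'
#' @param series A `fermenter_series` data.frame.
#' @param path CSV path.
#' @return `write_fermenter_csv` invisibly returns `path`;
#'   `read_fermenter_csv` returns the series.
#' @export
write_fermenter_csv <- function(series, path) {
  utils::write.csv(as.data.frame(series), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_fermenter_csv
#' @export
read_fermenter_csv <- function(path) {
  out <- utils::read.csv(path)
  class(out) <- c("fermenter_series", "data.frame")
  out
}

#' Load a scenario configuration from JSON
#'
#' The JSON holds any subset of [scenario_config()] fields; missing fields
#' take the scenario defaults. `energy` and `econ` blocks are rebuilt into
#' their parameter classes.
#'
#' @param path JSON file path.
#' @param scenario Scenario number used when the file omits it.
#' @return A [scenario_config()].
#' @export
read_scenario_config <- function(path, scenario = 1) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!is.null(raw$scenario)) scenario <- raw$scenario
  raw$scenario <- NULL
  if (!is.null(raw$energy)) {
    raw$energy <- do.call(energy_params, raw$energy)
  }
  if (!is.null(raw$econ)) {
    raw$econ <- do.call(econ_params, c(list(scenario = scenario), raw$econ))
  }
  scenario_config(scenario, overrides = raw)
}

# djb2-style hash of a serialized object, as provenance fingerprint
# (kept within 31 bits so the arithmetic stays exact in doubles).
config_hash <- function(x) {
  bytes <- as.integer(serialize(x, NULL, version = 2))
  h <- 5381
  for (b in bytes) h <- (h * 33 + b) %% 2147483647
  sprintf("%08x", as.integer(h))
}

# Provenance block embedded in every CLI artifact.
provenance <- function(config = NULL, seed = NULL) {
  list(package = "biovalor",
       version = as.character(utils::packageVersion("biovalor")),
       seed = seed,
       config_hash = if (!is.null(config)) config_hash(config) else NULL)
}
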