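#' Write and read run configuration files
#'
#' The configuration is a YAML document holding the population parameters
#' (fixed effects, IIV as log-scale SDs, residual error magnitudes), the
#' unbound-fraction and molecular-weight constants, the IIV reporting
#' convention and an optional default seed. Field names are stable and
#' round-trip losslessly through [read_config()].
#'
#' @param pop A population parameters object.
#' @param path Output file path.
#' @param seed Optional default seed recorded in the file.
#' @return `path`, invisibly.
#' @export
write_config <- function(pop, path, seed = NULL) {
  doc <- list(
    population = list(
      fixed = as.list(pop$fixed),
      iiv = as.list(pop$iiv),
      residual = pop$residual,
      fixed_flags = as.list(pop$fixed_flags),
      iiv_convention = pop$iiv_convention),
    constants = as.list(pop$constants))
  if (!is.null(seed)) doc$seed <- as.integer(seed)
  writeLines(yaml::as.yaml(doc, precision = 15), path)
  invisible(path)
}

#' @rdname write_config
#' @return For `read_config()`: a list with elements `pop` (a
#'   `population_parameters` object) and `seed` (or `NULL`).
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  doc <- yaml::read_yaml(path)
  pop <- list(
    fixed = unlist(doc$population$fixed),
    iiv = unlist(doc$population$iiv),
    residual = lapply(doc$population$residual, function(r) {
      r$add_fixed <- isTRUE(r$add_fixed); r
    }),
    constants = unlist(doc$constants),
    fixed_flags = unlist(doc$population$fixed_flags),
    iiv_convention = doc$population$iiv_convention)
  class(pop) <- "population_parameters"
  list(pop = pop, seed = doc$seed)
}
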