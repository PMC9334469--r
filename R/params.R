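#' Simulator parameters
#'
#' Loads the nested parameter list governing the virtual lung, injury
#' processes, gas exchange, hemodynamics, controller and protocol timing.
#' Defaults are shipped as a YAML config in `inst/extdata/default_params.yaml`
#' and can be replaced wholesale (`file`) or patched (`overrides`).
#'
#' @param file path to a YAML config; `NULL` uses the packaged defaults.
#' @param overrides named list merged recursively over the loaded config,
#'   e.g. `list(injury = list(lavage_shift_mean = 5))`.
#' @return nested named list of parameters.
#' @export
#' @examples
#' p <- pv_params()
#' p$lung$n_units
#' pv_params(overrides = list(lung = list(n_units = 50)))$lung$n_units
pv_params <- function(file = NULL, overrides = list()) {
  if (is.null(file)) {
    file <- system.file("extdata", "default_params.yaml", package = "pigvent")
  }
  p <- yaml::read_yaml(file)
  if (length(overrides)) p <- modifyList(p, overrides)
  p
}

#' Write a parameter list back to YAML
#'
#' @param params nested parameter list as returned by [pv_params()].
#' @param file destination path.
#' @return `file`, invisibly.
#' @export
pv_write_params <- function(params, file) {
  yaml::write_yaml(params, file)
  invisible(file)
}

# Overdistension compliance multiplier: ~1 at low PIP, sigmoid decline above.
# The sigmoid widens with consolidation: an injured, heterogeneous lung has a
# broader spread of regional distension thresholds than a healthy one.
od_factor <- function(pip, lung, consolidated = 0) {
  w <- lung$od_width *
    (1 + lung$od_width_consol_gain * min(consolidated, lung$od_width_consol_cap))
  sig <- 1 / (1 + exp((pip - lung$od_p50) / w))
  sig0 <- 1 / (1 + exp(-lung$od_p50 / w)) # normalize so od_factor(0) = 1
  lung$od_min + (1 - lung$od_min) * sig / sig0
}
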