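# YAML front ends for scenario and matching-criteria configuration.

#' Read a screen scenario from YAML
#'
#' Keys mirror the arguments of [screen_scenario()]; missing keys take
#' the defaults. A `bait_models` key, when present, is a list of
#' `{assembly, values, unit}` entries.
#'
#' @param path YAML file.
#' @return a `screen_scenario`.
#' @export
read_scenario_yaml <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (!is.null(cfg$bait_models)) {
    cfg$bait_models <- lapply(cfg$bait_models, function(b) {
      bait_model(b$assembly, unlist(b$values),
                 unit = if (is.null(b$unit)) "relative" else b$unit)
    })
    names(cfg$bait_models) <-
      vapply(cfg$bait_models, `[[`, "", "assembly_id")
  }
  do.call(screen_scenario, cfg)
}

#' Read matching criteria from YAML
#'
#' @param path YAML file with any of the [match_criteria()] arguments.
#' @return a `match_criteria`.
#' @export
read_criteria_yaml <- function(path) {
  do.call(match_criteria, yaml::read_yaml(path))
}
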