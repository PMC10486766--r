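#' Default run configuration
#'
#' The tunable parameters of the pipeline with their defaults: the hue cut
#' for the yellow class (0.167), the optional saturation gate (disabled), the
#' texture-analyzer trigger force (25 gf), the replicate policy ("mean"), the
#' prediction model ("model4"), and an optional seed.
#'
#' @return Named list (class `riceval_config`).
#' @export
default_config <- function() {
  structure(
    list(
      hue_threshold = 0.167,
      saturation_gate = NULL,
      trigger_force = 25,
      replicate_policy = "mean",
      model = "model4",
      seed = NULL
    ),
    class = "riceval_config"
  )
}

#' Read a run configuration from a YAML file
#'
#' Unknown keys are rejected and value ranges validated; missing keys take
#' their defaults. Configurations round-trip losslessly through
#' [write_config()].
#'
#' @param path YAML file.
#' @return A validated `riceval_config`.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop_config("config file not found: ", path)
  raw <- tryCatch(yaml::read_yaml(path),
                  error = function(e) stop_config("cannot parse config '",
                                                  path, "': ",
                                                  conditionMessage(e)))
  validate_config(utils::modifyList(unclass(default_config()), raw %||% list(),
                                    keep.null = TRUE),
                  source = path)
}

validate_config <- function(cfg, source = "config") {
  known <- names(default_config())
  extra <- setdiff(names(cfg), known)
  if (length(extra)) {
    stop_config(source, ": unknown key(s): ", paste(extra, collapse = ", "))
  }
  if (cfg$hue_threshold <= 0 || cfg$hue_threshold >= 1) {
    stop_config(source, ": hue_threshold must be in (0, 1)")
  }
  if (!is.null(cfg$saturation_gate) &&
      (cfg$saturation_gate < 0 || cfg$saturation_gate > 1)) {
    stop_config(source, ": saturation_gate must be in [0, 1]")
  }
  if (cfg$trigger_force <= 0) {
    stop_config(source, ": trigger_force must be positive")
  }
  if (!cfg$replicate_policy %in% c("mean", "none")) {
    stop_config(source, ": replicate_policy must be 'mean' or 'none'")
  }
  if (!cfg$model %in% c("model1", "model2", "model3", "model4")) {
    stop_config(source, ": model must be one of model1..model4")
  }
  structure(cfg, class = "riceval_config")
}

#' Write a run configuration to YAML
#'
#' @param cfg A `riceval_config`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_config <- function(cfg, path) {
  cfg <- validate_config(unclass(cfg))
  yaml::write_yaml(purrr::compact(unclass(cfg)), path)
  invisible(path)
}
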