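#' Save / load trained model checkpoints
#'
#' Single-file checkpoints bundling the configuration and all parameters
#' (RDS serialization). Works for `ecg_vae` and `radio_model` objects.
#'
#' @param model a trained model.
#' @param path checkpoint file path.
#' @return `save_checkpoint` returns `path` invisibly; `load_checkpoint`
#'   the restored model.
#' @export
save_checkpoint <- function(model, path) {
  stopifnot(inherits(model, c("ecg_vae", "radio_model")))
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  model <- readRDS(path)
  if (!inherits(model, c("ecg_vae", "radio_model")))
    stopf("not a radiosem checkpoint: %s", path)
  model
}

#' Read an experiment configuration from YAML
#'
#' Top-level keys mirror the arguments of [experiment_config()]; the
#' `ecg_vae:` and `radio:` sections hold model-config overrides.
#'
#' @param path YAML file.
#' @return an `experiment_config`.
#' @export
read_experiment_yaml <- function(path) {
  raw <- yaml::read_yaml(path)
  if (!is.null(raw$rhythm_mix)) raw$rhythm_mix <- unlist(raw$rhythm_mix)
  do.call(experiment_config, raw)
}
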