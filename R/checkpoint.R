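# Checkpoints and configuration files. A checkpoint is a portable list of
# weight arrays keyed by layer name, plus the configuration, buffers and
# pruning state, so a model round-trips exactly. Network configurations
# serialize to YAML.

#' Save a model checkpoint
#'
#' @param model a `slim3d_model`.
#' @param path output file (RDS).
#' @export
save_checkpoint <- function(model, path) {
  stopifnot(inherits(model, "slim3d_model"))
  ck <- list(format = "slim3d-checkpoint-1",
             config = unclass(model$config),
             layers = model$layers,
             prune = model$prune)
  saveRDS(ck, path)
  invisible(path)
}

#' Load a model checkpoint
#'
#' @param path checkpoint file written by [save_checkpoint()].
#' @return A `slim3d_model`.
#' @export
load_checkpoint <- function(path) {
  ck <- readRDS(path)
  if (!identical(ck$format, "slim3d-checkpoint-1"))
    stop("not a recognized checkpoint: ", path)
  # reconstructed directly (not via the constructor): a compacted model's
  # stage widths need not satisfy the constructor's monotonicity check
  structure(list(config = structure(ck$config,
                                    class = "slim3d_network_config"),
                 layers = ck$layers, prune = ck$prune),
            class = "slim3d_model")
}

#' Write a network configuration to YAML
#'
#' @param cfg a [network_config()].
#' @param path output YAML file.
#' @export
write_network_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "slim3d_network_config"))
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

#' Read a network configuration from YAML
#'
#' @param path YAML file written by [write_network_config()].
#' @return A [network_config()].
#' @export
read_network_config <- function(path) {
  do.call(network_config, yaml::read_yaml(path))
}
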