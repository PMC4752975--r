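# Run configuration: a YAML file (or nothing) merged over the package
# defaults, overridable field by field. Every artifact a run writes carries
# the merged snapshot plus the package version, so results are traceable to
# their settings.

#' Default run configuration
#'
#' Training hyperparameters at the published operating point (see
#' [ddi_train_config]), the default filter rule set, and pipeline paths
#' left empty.
#'
#' @return nested list of class `ddi_run_config`.
#' @export
default_run_config <- function() {
  structure(list(
    train = unclass(ddi_train_config()),
    filter_rules = unclass(default_filter_rules()),
    synth = unclass(synth_config())[c("n_sentences", "class_proportions",
                                      "drugs_per_sentence",
                                      "filter_trap_rate", "noise_rate",
                                      "seed")],
    pretrained_embeddings = NULL,
    no_filter = FALSE
  ), class = "ddi_run_config")
}

merge_config <- function(base, override) {
  for (nm in names(override)) {
    if (is.list(base[[nm]]) && is.list(override[[nm]]))
      base[[nm]] <- merge_config(base[[nm]], override[[nm]])
    else base[[nm]] <- override[[nm]]
  }
  base
}

#' Read a run configuration, merging a YAML file over the defaults
#'
#' @param path YAML file path, or NULL for pure defaults.
#' @param overrides named list applied after the file (flag-style
#'   overrides; nested lists merge field by field).
#' @return `ddi_run_config` list.
#' @export
read_run_config <- function(path = NULL, overrides = list()) {
  cfg <- unclass(default_run_config())
  if (!is.null(path)) {
    if (!file.exists(path)) stop("config file not found: ", path)
    cfg <- merge_config(cfg, yaml::read_yaml(path))
  }
  cfg <- merge_config(cfg, overrides)
  structure(cfg, class = "ddi_run_config")
}

#' Write the configuration snapshot carried by run artifacts
#'
#' @param cfg a `ddi_run_config`.
#' @param path output YAML path.
#' @export
write_config_snapshot <- function(cfg, path) {
  snap <- unclass(cfg)
  snap$tool_version <- as.character(utils::packageVersion("ddicnn"))
  yaml::write_yaml(snap, path)
  invisible(path)
}
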