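# Optional YAML configuration: a single file can override the pipeline's
# tunables (trim length, selection threshold, feature-extractor options,
# simulator parameters) for scripted runs.

#' Default pipeline configuration
#'
#' @param trim_s Edge trim in seconds (default 0.5).
#' @param threshold Feature-selection |r| threshold (default 0.7).
#' @param redundancy_threshold Redundancy-pruning |r| threshold
#'   (default 0.9).
#' @param val_fraction Grid-search validation fraction (default 0.2).
#' @param feature_opts A [feature_options()].
#' @param sim A [sim_config()].
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(trim_s = 0.5, threshold = 0.7,
                            redundancy_threshold = 0.9, val_fraction = 0.2,
                            feature_opts = feature_options(),
                            sim = sim_config()) {
  structure(list(trim_s = trim_s, threshold = threshold,
                 redundancy_threshold = redundancy_threshold,
                 val_fraction = val_fraction, feature_opts = feature_opts,
                 sim = sim),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' Top-level keys `trim_s`, `threshold`, `redundancy_threshold`,
#' `val_fraction` override scalars; a `features` mapping is passed to
#' [feature_options()] and a `simulator` mapping to [sim_config()]
#' (simulator vector fields such as `condition_av_targets` are given as
#' named mappings). Unknown keys raise an error rather than being silently
#' ignored.
#'
#' @param path Path to a YAML file.
#' @return A validated `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) stop("no such config file: ", path, call. = FALSE)
  y <- yaml::read_yaml(path)
  known <- c("trim_s", "threshold", "redundancy_threshold", "val_fraction",
             "features", "simulator")
  unknown <- setdiff(names(y), known)
  if (length(unknown)) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  fo <- do.call(feature_options, as.list(y$features))
  sim_args <- as.list(y$simulator)
  for (nm in c("condition_av_targets", "site_gains", "site_noise_sd",
               "site_gain_cv")) {
    if (!is.null(sim_args[[nm]])) sim_args[[nm]] <- unlist(sim_args[[nm]])
  }
  sim <- do.call(sim_config, sim_args)
  base <- pipeline_config(feature_opts = fo, sim = sim)
  for (nm in c("trim_s", "threshold", "redundancy_threshold",
               "val_fraction")) {
    if (!is.null(y[[nm]])) base[[nm]] <- y[[nm]]
  }
  base
}
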