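# Experiment configuration file interchange (YAML).

#' Write / read an experiment configuration file
#'
#' The configuration is stored as flat YAML with `sim.*` and `hmm.*`
#' sections mirroring [sim_config()] and [hmm_params()]; every field can be
#' overridden from the command line of the bundled CLI.
#'
#' @param cfg an [experiment_config()]
#' @param path YAML file
#' @return `path` (writer) / an `experiment_config` (reader)
#' @export
write_experiment_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "experiment_config"))
  if (!requireNamespace("yaml", quietly = TRUE))
    stop("the 'yaml' package is required for config files")
  x <- unclass_all(cfg)
  yaml::write_yaml(x, path)
  invisible(path)
}

#' @rdname write_experiment_config
#' @export
read_experiment_config <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE))
    stop("the 'yaml' package is required for config files")
  x <- yaml::read_yaml(path)
  experiment_config(
    sim = do.call(sim_config, x$sim),
    hmm = do.call(hmm_params, x$hmm),
    window_bp = x$window_bp, tol = x$tol,
    marker_panel_size = x$marker_panel_size,
    n_risk_minor = x$n_risk_minor, n_risk_major = x$n_risk_major,
    causal_or = x$causal_or, prevalence = x$prevalence)
}
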