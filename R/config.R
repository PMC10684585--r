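#' Default run configuration
#'
#' The full configuration tree used by the command-line pipelines: ACE
#' convergence controls, ensemble-fitting options, the synthetic scenario
#' specification, the shot counts to sweep, and the base seed. Stage-level
#' seeds are derived from the base seed (see [derive_seeds()]-style streams
#' in the run log) so any stage can be re-run in isolation.
#'
#' @return nested named list.
#' @export
default_config <- function() {
  list(
    ace = list(tol = 1e-6, max_iter = 100L),
    mstl = list(mode = "group", aggregate = "mean",
                variance_floor = 1e-8, clip_probabilities = FALSE),
    scenario = list(n_sources = 4L, n_classes = 6L, feature_dim = 64L,
                    separations = c(2.0, 1.0, 0.5, 0.0), noise_sd = 1.0),
    shots = c(1L, 5L, 10L, 20L),
    n_test_per_class = 10L,
    seed = 1L
  )
}

# strict recursive merge: every key in `user` must exist in `defaults`
merge_config <- function(defaults, user, path = "") {
  if (is.null(user)) return(defaults)
  unknown <- setdiff(names(user), names(defaults))
  if (length(unknown) > 0) {
    stop(sprintf("unknown config key(s)%s: %s",
                 if (nzchar(path)) paste0(" under ", path) else "",
                 paste(unknown, collapse = ", ")))
  }
  for (k in names(user)) {
    if (is.list(defaults[[k]]) && !is.null(names(defaults[[k]]))) {
      defaults[[k]] <- merge_config(defaults[[k]], user[[k]],
                                    paste0(path, k, "."))
    } else {
      defaults[[k]] <- user[[k]]
    }
  }
  defaults
}

#' Load a YAML run configuration
#'
#' Reads a YAML file and merges it over [default_config()]. Unknown keys are
#' rejected so typos fail loudly rather than silently running defaults.
#'
#' @param path YAML file path, or `NULL` for the defaults.
#' @return resolved configuration list.
#' @export
load_config <- function(path = NULL) {
  cfg <- default_config()
  if (!is.null(path)) {
    if (!file.exists(path)) stop(sprintf("missing config file: %s", path))
    cfg <- merge_config(cfg, yaml::read_yaml(path))
  }
  cfg
}

config_to_mstl <- function(cfg) {
  mstl_config(mode = cfg$mstl$mode, aggregate = cfg$mstl$aggregate,
              variance_floor = cfg$mstl$variance_floor,
              clip_probabilities = cfg$mstl$clip_probabilities,
              tol = cfg$ace$tol, max_iter = cfg$ace$max_iter)
}

config_to_scenario <- function(cfg, seed) {
  scenario_spec(n_sources = cfg$scenario$n_sources,
                n_classes = cfg$scenario$n_classes,
                feature_dim = cfg$scenario$feature_dim,
                separations = cfg$scenario$separations,
                noise_sd = cfg$scenario$noise_sd,
                seed = seed)
}
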