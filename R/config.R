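#' Load and validate a pipeline run configuration
#'
#' A single YAML file can fix the game geometry, simulator sampling rate,
#' statistics parameters and classifier grids for a whole pipeline run.
#' Every key is optional and defaults to the package defaults; unknown keys
#' are rejected so typos fail loudly rather than silently falling back.
#'
#' Recognised keys: `layout` (`target_distance_cm`, `target_radius_cm`,
#' `center_radius_cm`, `appearance_duration_s`), `sampling_rate_hz`,
#' `kinematics` (`smoothing`), `stats` (`n_boot`, `level`, `alpha`),
#' `classifier` (`kernels`, `costs`, `gammas`, `scale`, `class_weights`).
#'
#' @param path Path to a YAML file, or `NULL` for all defaults.
#' @return A list of class `run_config` with elements `layout`
#'   ([game_layout()]), `sampling_rate_hz`, `kinematics`, `stats` and
#'   `classifier` ([classifier_config()]).
#' @export
load_run_config <- function(path = NULL) {
  y <- if (is.null(path)) {
    list()
  } else {
    if (!file.exists(path)) abort(paste0("config file not found: ", path))
    yaml::read_yaml(path) %||% list()
  }
  known <- c("layout", "sampling_rate_hz", "kinematics", "stats",
             "classifier")
  unknown <- setdiff(names(y), known)
  if (length(unknown)) {
    abort(paste0("unknown config keys: ", paste(unknown, collapse = ", ")))
  }
  check_sub <- function(block, allowed) {
    extra <- setdiff(names(y[[block]]), allowed)
    if (length(extra)) {
      abort(paste0("unknown keys in config block '", block, "': ",
                   paste(extra, collapse = ", ")))
    }
  }
  check_sub("layout", c("target_distance_cm", "target_radius_cm",
                        "center_radius_cm", "appearance_duration_s"))
  check_sub("kinematics", "smoothing")
  check_sub("stats", c("n_boot", "level", "alpha"))
  check_sub("classifier", c("kernels", "costs", "gammas", "scale",
                            "class_weights"))

  lay <- do.call(game_layout, y$layout %||% list())
  cls_args <- y$classifier %||% list()
  for (k in c("costs", "gammas")) {
    if (!is.null(cls_args[[k]])) cls_args[[k]] <- as.numeric(cls_args[[k]])
  }
  cls <- do.call(classifier_config, cls_args)
  st <- y$stats %||% list()
  structure(
    list(
      layout = lay,
      sampling_rate_hz = y$sampling_rate_hz %||% 60,
      kinematics = list(smoothing = isTRUE(y$kinematics$smoothing)),
      stats = list(
        n_boot = st$n_boot %||% 10000,
        level = st$level %||% 0.95,
        alpha = st$alpha %||% 0.05
      ),
      classifier = cls
    ),
    class = "run_config"
  )
}
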