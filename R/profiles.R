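#' Impairment profiles: the kinematic targets a simulated group should hit
#'
#' An impairment profile fixes, per clock direction, the median and
#' log-normal dispersion of the three reach parameters (maximum speed,
#' average speed, total time), plus a per-target miss probability and a
#' log-normal reaction-time distribution. The session simulator draws each
#' hand's reach parameters from these distributions, so the cohort medians of
#' the *extracted* features recover the configured medians.
#'
#' Dispersion can be given directly (`*_sigma` columns, log scale) or
#' implied by interval bounds (`*_lo`, `*_hi`), in which case
#' `sigma = (log(hi) - log(lo)) / (2 * 1.96)`, i.e. the 2.5th/97.5th
#' population quantiles of the fitted log-normal span the interval.
#'
#' A profile is rejected unless, for every direction, the implied median
#' path length `avg_speed * total_time` is at least the straight-line
#' distance a scored reach must cover (centre-circle edge to target-disc
#' edge) and the median maximum speed is at least the median average speed.
#'
#' @param directions A data frame with one row per direction `0:11` and
#'   columns `direction`, `max_speed_median`, `avg_speed_median`,
#'   `total_time_median`, plus either `*_lo`/`*_hi` or `*_sigma` for each
#'   parameter. Speeds in cm/s, times in s.
#' @param label The group label the profile generates (`"CTS"`, `"non-CTS"`
#'   or `"unknown"`).
#' @param miss_prob Probability that any one target appearance is missed;
#'   a scalar or a length-12 vector (one probability per direction).
#' @param reaction_median_s,reaction_sigma Log-normal reaction time
#'   (target appearance to centre exit); it precedes the scored window and
#'   does not enter any feature.
#' @param layout The [game_layout()] the profile must be feasible for.
#' @return An object of class `impairment_profile`.
#' @seealso [control_profile()], [cts_profile()], [read_profile()],
#'   [simulate_session()]
#' @export
impairment_profile <- function(directions, label,
                               miss_prob = 0.05,
                               reaction_median_s = 0.25,
                               reaction_sigma = 0.2,
                               layout = game_layout()) {
  label <- match.arg(label, c("CTS", "non-CTS", "unknown"))
  stopifnot(is.data.frame(directions),
            length(miss_prob) %in% c(1L, 12L),
            all(miss_prob >= 0), all(miss_prob <= 1),
            reaction_median_s > 0, reaction_sigma >= 0)
  d <- tibble::as_tibble(directions)
  if (!setequal(d$direction, 0:11) || nrow(d) != 12L) {
    abort("`directions` must have exactly one row per direction 0..11")
  }
  d <- d[order(d$direction), , drop = FALSE]

  for (p in c("max_speed", "avg_speed", "total_time")) {
    med <- d[[paste0(p, "_median")]]
    if (is.null(med) || any(!is.finite(med)) || any(med <= 0)) {
      abort(sprintf("`%s_median` must be positive and finite", p))
    }
    sig_col <- paste0(p, "_sigma")
    if (is.null(d[[sig_col]])) {
      lo <- d[[paste0(p, "_lo")]]
      hi <- d[[paste0(p, "_hi")]]
      if (is.null(lo) || is.null(hi)) {
        abort(sprintf("`%s` needs either a sigma or lo/hi bounds", p))
      }
      if (any(lo <= 0) || any(hi <= lo)) {
        abort(sprintf("`%s` bounds must satisfy 0 < lo < hi", p))
      }
      d[[sig_col]] <- (log(hi) - log(lo)) / (2 * stats::qnorm(0.975))
    }
    if (any(d[[sig_col]] < 0)) abort(sprintf("`%s_sigma` must be >= 0", p))
  }

  if (any(d$max_speed_median < d$avg_speed_median)) {
    abort("median max_speed must be >= median avg_speed in every direction")
  }
  chord <- reach_chord_cm(layout)
  path <- d$avg_speed_median * d$total_time_median
  if (any(path < chord)) {
    bad <- d$direction[path < chord]
    abort(sprintf(
      "infeasible profile: implied median path length < %.2f cm (straight reach) in direction(s) %s",
      chord, paste(bad, collapse = ", ")
    ))
  }

  keep <- c("direction",
            paste0(rep(c("max_speed", "avg_speed", "total_time"), each = 2),
                   c("_median", "_sigma")))
  structure(
    list(
      label = label,
      miss_prob = miss_prob,
      reaction_median_s = reaction_median_s,
      reaction_sigma = reaction_sigma,
      directions = d[keep],
      layout = layout
    ),
    class = "impairment_profile"
  )
}

#' @export
print.impairment_profile <- function(x, ...) {
  cat(sprintf("<impairment_profile> label %s, miss probability %.2f\n",
              x$label, x$miss_prob))
  print(x$directions)
  invisible(x)
}

#' Read an impairment profile from YAML
#'
#' The YAML schema matches the files shipped in `inst/extdata`: top-level
#' `label`, `miss_prob`, `reaction_time: {median_s, sigma_log}` and a
#' `directions` list whose entries give `[median, lo, hi]` triples for
#' `max_speed`, `avg_speed` and `total_time`.
#'
#' @param path Path to a profile YAML file.
#' @param layout The [game_layout()] used for feasibility checks.
#' @return An [impairment_profile()].
#' @export
read_profile <- function(path, layout = game_layout()) {
  if (!file.exists(path)) abort(paste0("profile file not found: ", path))
  y <- yaml::read_yaml(path)
  need <- c("label", "directions")
  miss <- setdiff(need, names(y))
  if (length(miss)) {
    abort(paste0("profile YAML is missing fields: ", paste(miss, collapse = ", ")))
  }
  rows <- lapply(y$directions, function(e) {
    tibble::tibble(
      direction = as.integer(e$direction),
      max_speed_median = e$max_speed[1], max_speed_lo = e$max_speed[2],
      max_speed_hi = e$max_speed[3],
      avg_speed_median = e$avg_speed[1], avg_speed_lo = e$avg_speed[2],
      avg_speed_hi = e$avg_speed[3],
      total_time_median = e$total_time[1], total_time_lo = e$total_time[2],
      total_time_hi = e$total_time[3]
    )
  })
  impairment_profile(
    directions = dplyr::bind_rows(rows),
    label = y$label,
    miss_prob = y$miss_prob %||% 0.05,
    reaction_median_s = y$reaction_time$median_s %||% 0.25,
    reaction_sigma = y$reaction_time$sigma_log %||% 0.2,
    layout = layout
  )
}

#' Default group profiles
#'
#' The shipped calibrations: per-direction medians and interval bounds of
#' the three reach parameters for the non-CTS (control) and CTS groups, as
#' published for the original 11 control and 29 CTS hands. They are the
#' default study conditions for [simulate_cohort()].
#'
#' @param layout The [game_layout()] used for feasibility checks.
#' @return An [impairment_profile()].
#' @export
control_profile <- function(layout = game_layout()) {
  read_profile(
    system.file("extdata", "control_profile.yaml", package = "thumbscreen",
                mustWork = TRUE),
    layout = layout
  )
}

#' @rdname control_profile
#' @export
cts_profile <- function(layout = game_layout()) {
  read_profile(
    system.file("extdata", "cts_profile.yaml", package = "thumbscreen",
                mustWork = TRUE),
    layout = layout
  )
}
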