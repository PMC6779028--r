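#' Welch two-sample t-test
#'
#' Compares group means without assuming equal variances:
#' `t = (mean(x) - mean(y)) / sqrt(s2x/nx + s2y/ny)` with
#' Welch--Satterthwaite degrees of freedom and a two-sided p-value from the
#' Student-t distribution. A thin, typed wrapper around [stats::t.test()]
#' that returns a one-row tibble suitable for row-binding across many cells.
#'
#' @param x,y Numeric samples, each with at least 2 values and non-zero
#'   variance.
#' @return A one-row tibble: `t_stat`, `df`, `p_value`.
#' @examples
#' welch_test(c(1, 2, 3, 4), c(2, 4, 6, 8))
#' @export
welch_test <- function(x, y) {
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) < 2 || length(y) < 2) {
    abort("welch_test needs at least 2 values per sample")
  }
  if (var(x) == 0 || var(y) == 0) {
    abort("welch_test needs non-zero variance in both samples")
  }
  ht <- stats::t.test(x, y, var.equal = FALSE)
  tibble::tibble(
    t_stat = unname(ht$statistic),
    df = unname(ht$parameter),
    p_value = ht$p.value
  )
}

#' Percentile-bootstrap confidence interval for a median
#'
#' Resamples the data with replacement `n_boot` times, takes the median of
#' each resample, and reports the `(1-level)/2` and `(1+level)/2` quantiles
#' of the bootstrap medians. Distribution-free and deterministic for a given
#' seed.
#'
#' @param x Numeric sample with at least 3 values.
#' @param level Confidence level (default 0.95).
#' @param n_boot Number of bootstrap resamples (default 10000).
#' @param seed Integer seed for the resampling.
#' @return A one-row tibble: `median`, `ci_lo`, `ci_hi`.
#' @examples
#' median_ci(rlnorm(29), n_boot = 999, seed = 1)
#' @export
median_ci <- function(x, level = 0.95, n_boot = 10000, seed = 1) {
  x <- as.numeric(x)
  if (length(x) < 3) abort("median_ci needs at least 3 values")
  stopifnot(level > 0, level < 1, n_boot >= 1)
  n <- length(x)
  boots <- withr_seed(seed, {
    m <- matrix(sample(x, n * n_boot, replace = TRUE), nrow = n_boot)
    apply(m, 1, median)
  })
  qs <- unname(quantile(boots, c((1 - level) / 2, (1 + level) / 2),
                        type = 7))
  tibble::tibble(median = median(x), ci_lo = qs[1], ci_hi = qs[2])
}

#' Per-direction group comparison of the three reach parameters
#'
#' The radar-chart analysis layer: for each of the 36 cells (3 parameters x
#' 12 clock directions) it reports the group medians with bootstrap 95% CIs
#' and a two-sided Welch t-test between the CTS and non-CTS hands. Each cell
#' is tested at `alpha` with no multiple-testing correction -- the
#' screening-study convention this package mirrors; interpret the per-cell
#' flags accordingly.
#'
#' @param table A feature table ([features_to_table()]) whose `label` column
#'   contains both `"CTS"` and `"non-CTS"`, each with at least 3 hands.
#' @param level Confidence level for the median CIs.
#' @param n_boot Bootstrap resamples per CI; `0` skips CI computation
#'   (`NA` bounds), useful in simulation loops that only need p-values.
#' @param seed Integer seed for the bootstrap.
#' @param alpha Significance threshold for the `significant` flag.
#' @return A tibble of class `cts_comparison` with 36 rows and columns
#'   `parameter`, `direction`, `median_control`, `ci_lo_control`,
#'   `ci_hi_control`, `median_cts`, `ci_lo_cts`, `ci_hi_cts`, `t_stat`,
#'   `df`, `p_value`, `significant`.
#' @examples
#' \donttest{
#' cohort <- simulate_cohort(n_control = 11, n_cts = 29, seed = 3)
#' tab <- features_to_table(lapply(cohort, extract_features))
#' compare_groups(tab, n_boot = 999)
#' }
#' @export
compare_groups <- function(table, level = 0.95, n_boot = 10000, seed = 1,
                           alpha = 0.05) {
  stopifnot(is.data.frame(table), "label" %in% names(table))
  for (lab in c("CTS", "non-CTS")) {
    if (sum(table$label == lab) < 3) {
      abort(sprintf("compare_groups needs at least 3 hands labelled '%s'", lab))
    }
  }
  params <- c(maxspeed_cmps = "max_speed", avgspeed_cmps = "avg_speed",
              totaltime_s = "total_time")
  is_cts <- table$label == "CTS"

  rows <- vector("list", 36L)
  k <- 0L
  for (d in 0:11) {
    for (suffix in names(params)) {
      col <- sprintf("d%02d_%s", d, suffix)
      x_ctrl <- table[[col]][!is_cts]
      x_cts <- table[[col]][is_cts]
      wt <- welch_test(x_ctrl, x_cts)
      if (n_boot > 0) {
        ci_c <- median_ci(x_ctrl, level, n_boot, seed = seed + 2L * k)
        ci_t <- median_ci(x_cts, level, n_boot, seed = seed + 2L * k + 1L)
      } else {
        ci_c <- tibble::tibble(median = median(x_ctrl), ci_lo = NA_real_,
                               ci_hi = NA_real_)
        ci_t <- tibble::tibble(median = median(x_cts), ci_lo = NA_real_,
                               ci_hi = NA_real_)
      }
      k <- k + 1L
      rows[[k]] <- tibble::tibble(
        parameter = params[[suffix]], direction = d,
        median_control = ci_c$median, ci_lo_control = ci_c$ci_lo,
        ci_hi_control = ci_c$ci_hi,
        median_cts = ci_t$median, ci_lo_cts = ci_t$ci_lo,
        ci_hi_cts = ci_t$ci_hi,
        t_stat = wt$t_stat, df = wt$df, p_value = wt$p_value,
        significant = wt$p_value < alpha
      )
    }
  }
  out <- dplyr::bind_rows(rows)
  out <- out[order(match(out$parameter, c("max_speed", "avg_speed", "total_time")),
                   out$direction), ]
  class(out) <- c("cts_comparison", class(out))
  attr(out, "alpha") <- alpha
  attr(out, "n_control") <- sum(!is_cts)
  attr(out, "n_cts") <- sum(is_cts)
  out
}

#' Write the group-comparison report CSV
#'
#' The machine-readable twin of the per-direction radar tables: one row per
#' parameter x direction cell, with group medians, CI bounds, Welch
#' statistic, degrees of freedom and p-value.
#'
#' @param comparison A [compare_groups()] result.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_comparison_csv <- function(comparison, path) {
  stopifnot(inherits(comparison, "cts_comparison"))
  utils::write.csv(as.data.frame(comparison), path, row.names = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' Radar plot of a group comparison
#'
#' One polar panel per parameter, with 12 o'clock at the top and directions
#' advancing clockwise as on a clock face; ribbons span the bootstrap CIs
#' and starred directions differ between groups at the comparison's alpha.
#'
#' @param object A [compare_groups()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.cts_comparison <- function(object, ...) {
  df <- tidyr::pivot_longer(
    tibble::as_tibble(object),
    cols = c("median_control", "median_cts"),
    names_to = "group", values_to = "median",
    names_prefix = "median_"
  )
  df$ci_lo <- ifelse(df$group == "control", df$ci_lo_control, df$ci_lo_cts)
  df$ci_hi <- ifelse(df$group == "control", df$ci_hi_control, df$ci_hi_cts)
  df$group <- ifelse(df$group == "control", "non-CTS", "CTS")
  df$parameter <- factor(
    df$parameter,
    levels = c("max_speed", "avg_speed", "total_time"),
    labels = c("max speed (cm/s)", "avg speed (cm/s)", "total time (s)")
  )
  stars <- df[df$significant & df$group == "CTS", ]
  ggplot2::ggplot(df, ggplot2::aes(
    x = .data$direction, y = .data$median,
    colour = .data$group, fill = .data$group, group = .data$group
  )) +
    ggplot2::geom_ribbon(
      ggplot2::aes(ymin = .data$ci_lo, ymax = .data$ci_hi),
      alpha = 0.15, colour = NA
    ) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1) +
    ggplot2::geom_text(
      data = stars, label = "*", colour = "black", vjust = 0, size = 5,
      ggplot2::aes(y = .data$ci_hi)
    ) +
    ggplot2::coord_polar(start = -pi / 12) +
    ggplot2::scale_x_continuous(
      breaks = 0:11, labels = c(12, 1:11), limits = c(-0.5, 11.5)
    ) +
    ggplot2::facet_wrap(~parameter, scales = "free_y") +
    ggplot2::labs(
      x = "clock direction", y = "group median (95% CI)",
      colour = NULL, fill = NULL,
      title = "Thumb-reach kinematics by clock direction",
      subtitle = "* Welch test below the comparison alpha (uncorrected)"
    ) +
    ggplot2::theme_minimal()
}

#' @export
print.cts_comparison <- function(x, ...) {
  cat(sprintf(
    "<cts_comparison> %d control vs %d CTS hands; %d/%d cells significant at alpha = %.3g\n",
    attr(x, "n_control"), attr(x, "n_cts"),
    sum(x$significant), nrow(x), attr(x, "alpha")
  ))
  NextMethod()
}
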