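# geometric tolerance (cm) for inside/outside tests on circles
.geom_tol <- 1e-9

#' Segment a session's touch stream into per-direction reaches
#'
#' For each clock direction the scored reach window is chosen from that
#' direction's target events: the appearance on which the target was
#' collected, or the first appearance if both were missed. Within the window
#' the reach starts when the thumb first crosses the central circle's
#' boundary (located by linear interpolation between the straddling samples,
#' so dwell time inside the centre is excluded) and ends when the target is
#' collected -- the first touching sample inside the target disc -- or at the
#' target's resolution time if it was missed.
#'
#' @param session A valid [cts_session()].
#' @return A list of reach segments, one per direction that produced one.
#'   Each segment is a list with `direction`, `t_start`, `t_end`,
#'   `provenance` (`"collected_1"`, `"collected_2"` or `"missed"`) and
#'   `samples` (a data frame restricted to the reach window, beginning with
#'   the interpolated boundary-crossing point). Directions whose window
#'   yielded fewer than two usable samples are listed in the
#'   `"unsegmentable"` attribute.
#' @export
segment_reaches <- function(session) {
  stopifnot(inherits(session, "cts_session"))
  lay <- session$layout
  sm <- session$samples
  t <- sm$t; x <- sm$x; y <- sm$y; touching <- sm$touching
  r <- sqrt(x^2 + y^2)
  r0 <- lay$center_radius_cm
  tpos <- target_position(lay, 0:11)
  rt2 <- (lay$target_radius_cm + .geom_tol)^2

  tg_dir <- session$targets$direction
  tg_app <- session$targets$appearance_index
  tg_t0 <- session$targets$t_appear
  tg_t1 <- session$targets$t_resolve
  tg_out <- session$targets$outcome

  segments <- list()
  unseg <- integer()

  for (d in sort(unique(tg_dir[!is.na(tg_dir)]))) {
    idx <- which(!is.na(tg_dir) & tg_dir == d)
    hit <- idx[tg_out[idx] == "collected"]
    ev <- if (length(hit)) hit[1L] else idx[which.min(tg_t0[idx])]
    collected <- tg_out[ev] == "collected"
    prov <- if (collected) paste0("collected_", tg_app[ev]) else "missed"

    win <- which(t >= tg_t0[ev] & t <= tg_t1[ev])
    if (!length(win) || !any(touching[win])) {
      abort(sprintf(
        "direction %d has a target event but no touching samples in its window",
        d
      ))
    }

    # end of the reach: collection contact, or timeout for a miss
    if (collected) {
      d2 <- (x[win] - tpos[d + 1L, 1L])^2 + (y[win] - tpos[d + 1L, 2L])^2
      inside_target <- touching[win] & d2 <= rt2
      t_end <- if (any(inside_target)) t[win[which(inside_target)[1L]]] else tg_t1[ev]
    } else {
      t_end <- tg_t1[ev]
    }

    # start of the reach: first centre-boundary crossing before t_end
    sub <- win[t[win] <= t_end]
    inside <- r[sub] <= r0 + .geom_tol
    cross <- which(inside[-length(inside)] & !inside[-1L])
    if (length(cross)) {
      i <- sub[cross[1L]]; j <- sub[cross[1L] + 1L]
      f <- (r0 - r[i]) / (r[j] - r[i])
      t_start <- t[i] + f * (t[j] - t[i])
      x0 <- x[i] + f * (x[j] - x[i])
      y0 <- y[i] + f * (y[j] - y[i])
    } else {
      # thumb never registered inside the centre during the window: fall back
      # to the first touching sample so degraded recordings still segment
      first <- sub[which(touching[sub])[1L]]
      t_start <- t[first]; x0 <- x[first]; y0 <- y[first]
    }

    keep <- win[t[win] > t_start + .geom_tol & t[win] <= t_end]
    nseg <- length(keep) + 1L
    seg_samples <- structure(
      list(
        t = c(t_start, t[keep]),
        x = c(x0, x[keep]),
        y = c(y0, y[keep]),
        touching = c(TRUE, touching[keep])
      ),
      class = "data.frame", row.names = c(NA_integer_, -nseg)
    )
    if (nseg < 2L || t_end <= t_start) {
      unseg <- c(unseg, d)
      next
    }
    segments[[length(segments) + 1L]] <- list(
      direction = d, t_start = t_start, t_end = t_end,
      provenance = prov, samples = seg_samples
    )
  }
  attr(segments, "unsegmentable") <- unseg
  segments
}

#' Per-reach kinematic parameters
#'
#' Computes the three screening parameters of one reach from raw finite
#' differences, with no smoothing: instantaneous speed is the Euclidean
#' displacement over the time step between consecutive samples while the
#' thumb is in contact; `max_speed` is the largest of these; `avg_speed` is
#' the path length divided by the reach duration; `total_time` is the
#' duration from centre exit to target contact (or timeout). Lift-off gaps
#' (`touching = FALSE`) contribute no path length -- the screen cannot see a
#' lifted thumb -- but the clock keeps running.
#'
#' @param segment One element of [segment_reaches()] output.
#' @param smoothing Apply a 3-sample moving average to the positions before
#'   differencing (default `FALSE`: raw finite differences, matching the
#'   recording; smoothing damps single-sample jitter and can only lower the
#'   measured peak speed).
#' @return A one-row tibble: `direction`, `max_speed_cmps`, `avg_speed_cmps`,
#'   `total_time_s`, `provenance`.
#' @export
compute_kinematics <- function(segment, smoothing = FALSE) {
  k <- .reach_kinematics(segment, smoothing)
  tibble::tibble(
    direction = as.integer(segment$direction),
    max_speed_cmps = k[1], avg_speed_cmps = k[2], total_time_s = k[3],
    provenance = segment$provenance
  )
}

.smooth3 <- function(z) {
  n <- length(z)
  if (n < 3L) return(z)
  c(z[1L], (z[-c(1L, 2L)] + z[-c(1L, n)] + z[-c(n - 1L, n)]) / 3, z[n])
}

.reach_kinematics <- function(segment, smoothing = FALSE) {
  s <- segment$samples
  if (isTRUE(smoothing)) {
    s$x <- .smooth3(s$x)
    s$y <- .smooth3(s$y)
  }
  n <- length(s$t)
  if (n < 2L) abort("a reach segment needs at least 2 samples")
  dt <- s$t[-1L] - s$t[-n]
  if (any(dt == 0)) abort("duplicate timestamps in reach segment")
  pair_touching <- s$touching[-n] & s$touching[-1L]
  if (!any(pair_touching)) abort("reach segment has no touching sample pairs")
  step <- sqrt((s$x[-1L] - s$x[-n])^2 + (s$y[-1L] - s$y[-n])^2)[pair_touching]
  total_time <- segment$t_end - segment$t_start
  c(max(step / dt[pair_touching]), sum(step) / total_time, total_time)
}

#' Extract the 36-value feature vector of one hand
#'
#' Segments the session and computes maximum speed, average speed and total
#' time for each of the twelve clock directions: 36 parameters per hand.
#' The canonical ordering is direction-major -- `d00_maxspeed_cmps`,
#' `d00_avgspeed_cmps`, `d00_totaltime_s`, `d01_maxspeed_cmps`, ... ,
#' `d11_totaltime_s` -- and is the column order used throughout the package.
#'
#' @param session A valid [cts_session()].
#' @param smoothing Passed to [compute_kinematics()].
#' @return An object of class `reach_features`: a list with `hand_id`,
#'   `label` and `kinematics`, a 12-row tibble (one row per direction).
#'   Use [feature_values()] for the flat named 36-vector and
#'   [features_to_table()] to combine hands into an analysis table.
#' @examples
#' f <- extract_features(simulate_session(control_profile(), seed = 1))
#' f$kinematics
#' @export
extract_features <- function(session, smoothing = FALSE) {
  segs <- segment_reaches(session)
  dirs <- vapply(segs, `[[`, integer(1), "direction")
  missing <- setdiff(0:11, dirs)
  missing <- sort(unique(c(missing, attr(segs, "unsegmentable"))))
  if (length(missing)) {
    abort(paste0(
      "cannot extract features: no reach segment for direction(s) ",
      paste(missing, collapse = ", ")
    ))
  }
  vals <- vapply(segs, .reach_kinematics, numeric(3), smoothing = smoothing)
  kin <- tibble::tibble(
    direction = as.integer(dirs),
    max_speed_cmps = vals[1L, ], avg_speed_cmps = vals[2L, ],
    total_time_s = vals[3L, ],
    provenance = vapply(segs, `[[`, character(1), "provenance")
  )
  kin <- kin[order(kin$direction), , drop = FALSE]
  structure(
    list(hand_id = session$hand_id, label = session$label, kinematics = kin),
    class = "reach_features"
  )
}

#' @export
print.reach_features <- function(x, ...) {
  cat(sprintf("<reach_features> hand %s [%s]\n", x$hand_id, x$label))
  print(x$kinematics)
  invisible(x)
}

#' Canonical feature column names
#'
#' @return Character vector of the 36 feature names in canonical
#'   direction-major order.
#' @export
feature_cols <- function() {
  as.vector(t(outer(
    sprintf("d%02d", 0:11),
    c("maxspeed_cmps", "avgspeed_cmps", "totaltime_s"),
    paste, sep = "_"
  )))
}

#' @rdname extract_features
#' @param features A `reach_features` object.
#' @export
feature_values <- function(features) {
  stopifnot(inherits(features, "reach_features"))
  k <- features$kinematics
  v <- as.vector(t(as.matrix(
    k[order(k$direction), c("max_speed_cmps", "avg_speed_cmps", "total_time_s")]
  )))
  setNames(v, feature_cols())
}

#' Combine per-hand feature vectors into an analysis table
#'
#' @param features_list A list of `reach_features` objects sharing the
#'   canonical ordering.
#' @return A tibble with one row per hand: `hand_id`, `label` and the 36
#'   feature columns of [feature_cols()]. With an empty list, the 38-column
#'   header with zero rows.
#' @export
features_to_table <- function(features_list) {
  cols <- feature_cols()
  if (length(features_list) == 0L) {
    out <- c(
      list(hand_id = character(), label = character()),
      setNames(rep(list(numeric()), length(cols)), cols)
    )
    return(tibble::as_tibble(out))
  }
  rows <- lapply(features_list, function(f) {
    v <- feature_values(f)
    if (!identical(names(v), cols)) abort("feature ordering mismatch")
    tibble::as_tibble_row(c(
      list(hand_id = f$hand_id, label = f$label), as.list(v)
    ))
  })
  dplyr::bind_rows(rows)
}

#' Read and write the feature-table CSV
#'
#' The on-disk twin of [features_to_table()]: UTF-8, `.` decimal point,
#' header `hand_id,label,d00_maxspeed_cmps,...,d11_totaltime_s`. Values are
#' written with enough digits to round-trip exactly.
#'
#' @param table A feature table as returned by [features_to_table()].
#' @param path File path.
#' @return `read_feature_csv()` returns the feature tibble; the writer
#'   returns `path` invisibly.
#' @export
write_feature_csv <- function(table, path) {
  stopifnot(is.data.frame(table))
  df <- as.data.frame(table)
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], function(z) sprintf("%.17g", z))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_feature_csv
#' @export
read_feature_csv <- function(path) {
  if (!file.exists(path)) abort(paste0("feature CSV not found: ", path))
  df <- utils::read.csv(path, stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  need <- c("hand_id", "label", feature_cols())
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    abort(paste0("feature CSV is missing columns: ", paste(miss, collapse = ", ")))
  }
  df$hand_id <- as.character(df$hand_id)
  tibble::as_tibble(df[need])
}
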