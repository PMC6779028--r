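#' Construct a thumb-reach session
#'
#' A session is one hand's complete game run: the layout it was played on,
#' the ordered log of target events (directional targets plus return-to-centre
#' targets) and the raw touch stream. Directional targets carry a clock
#' direction 0-11; return-to-centre targets carry `NA` in the `direction`
#' column (serialised as `"CENTER"`).
#'
#' @param hand_id Identifier for the hand.
#' @param label `"CTS"`, `"non-CTS"` or `"unknown"`.
#' @param layout A [game_layout()].
#' @param targets Data frame with columns `direction` (integer 0-11 or `NA`
#'   for centre targets), `appearance_index` (1 or 2), `t_appear`,
#'   `t_resolve` (seconds), `outcome` (`"collected"` or `"missed"`).
#' @param samples Data frame with columns `t` (seconds, strictly increasing),
#'   `x`, `y` (centimetres in layout coordinates) and `touching` (logical).
#' @param pixels_per_cm Calibration scalar; only used when reading raw
#'   pixel-coordinate recordings, stored for provenance.
#' @return An object of class `cts_session`.
#' @seealso [validate_session()], [read_session_json()], [simulate_session()]
#' @export
cts_session <- function(hand_id, label, layout, targets, samples,
                        pixels_per_cm = 1) {
  label <- match.arg(label, c("CTS", "non-CTS", "unknown"))
  targets <- tibble::as_tibble(targets)
  samples <- tibble::as_tibble(samples)
  stopifnot(
    all(c("direction", "appearance_index", "t_appear", "t_resolve", "outcome")
        %in% names(targets)),
    all(c("t", "x", "y", "touching") %in% names(samples))
  )
  structure(
    list(
      hand_id = as.character(hand_id),
      label = label,
      layout = layout,
      targets = targets,
      samples = samples,
      pixels_per_cm = pixels_per_cm
    ),
    class = "cts_session"
  )
}

#' @export
print.cts_session <- function(x, ...) {
  n_dir <- sum(!is.na(x$targets$direction))
  cat(sprintf(
    "<cts_session> hand %s [%s]: %d directional targets, %d touch samples, %.1f s\n",
    x$hand_id, x$label, n_dir, nrow(x$samples),
    if (nrow(x$samples)) max(x$samples$t) else 0
  ))
  invisible(x)
}

#' Check a session against the protocol invariants
#'
#' Runs every structural check of the session data model and returns all
#' violations found, not just the first: direction coverage (each of the 12
#' directions appears at least once), strictly increasing sample timestamps,
#' target events resolving after they appear, appearance indices in `{1, 2}`
#' with a second appearance only after a miss, non-empty touch stream and a
#' positive calibration scalar. Violations are data, not errors, so a caller
#' can report them all at once.
#'
#' @param session A [cts_session()].
#' @return A tibble with columns `field` and `message`; zero rows means the
#'   session is valid.
#' @examples
#' s <- simulate_session(control_profile(), seed = 1)
#' validate_session(s)   # 0 rows
#' @export
validate_session <- function(session) {
  stopifnot(inherits(session, "cts_session"))
  bad <- list()
  note <- function(field, message) {
    bad[[length(bad) + 1L]] <<- tibble::tibble(field = field, message = message)
  }

  tg <- session$targets
  sm <- session$samples

  dirs <- tg$direction[!is.na(tg$direction)]
  missing_dirs <- setdiff(0:11, dirs)
  if (length(missing_dirs)) {
    note("direction coverage", paste0(
      "directions never targeted: ", paste(missing_dirs, collapse = ", ")
    ))
  }
  if (any(!dirs %in% 0:11)) {
    note("direction range", "directional targets must have direction in 0..11")
  }

  counts <- table(dirs)
  if (any(counts > 2)) {
    note("appearance count", paste0(
      "direction appeared more than twice: ",
      paste(names(counts)[counts > 2], collapse = ", ")
    ))
  }
  if (!all(tg$appearance_index %in% c(1L, 2L))) {
    note("appearance_index", "appearance_index must be 1 or 2")
  }
  if (!all(tg$outcome %in% c("collected", "missed"))) {
    note("outcome", "outcome must be 'collected' or 'missed'")
  }
  if (any(tg$t_resolve <= tg$t_appear)) {
    note("target timing", "every target must resolve after it appears")
  }
  # a second appearance requires the first to have been missed
  second <- tg[!is.na(tg$direction) & tg$appearance_index == 2L, ]
  if (nrow(second)) {
    for (d in second$direction) {
      first <- tg[!is.na(tg$direction) & tg$direction == d &
                    tg$appearance_index == 1L, ]
      if (nrow(first) == 0L || first$outcome[1] != "missed") {
        note("appearance order", sprintf(
          "direction %d has a second appearance without a missed first", d
        ))
      }
    }
  }

  if (nrow(sm) == 0L) {
    note("samples", "sample stream is empty")
  } else if (any(diff(sm$t) <= 0)) {
    note("sample monotonicity", "sample timestamps must be strictly increasing")
  }
  if (nrow(sm) && any(sm$t < 0)) {
    note("sample timing", "sample timestamps must be non-negative")
  }
  if (!is.numeric(session$pixels_per_cm) || session$pixels_per_cm <= 0) {
    note("pixels_per_cm", "calibration scalar must be positive")
  }

  if (length(bad)) dplyr::bind_rows(bad) else {
    tibble::tibble(field = character(), message = character())
  }
}

#' Read and write session JSON
#'
#' One JSON object per hand holds the full session: identification, layout,
#' target events and the touch stream. Coordinates may be recorded in screen
#' pixels (`"units": "px"`), in which case they are divided by
#' `pixels_per_cm` on read; the writer always emits centimetres.
#'
#' @param path File path.
#' @return `read_session_json()` returns a [cts_session()];
#'   `write_session_json()` returns `path` invisibly.
#' @export
read_session_json <- function(path) {
  if (!file.exists(path)) abort(paste0("session file not found: ", path))
  j <- tryCatch(
    jsonlite::fromJSON(path, simplifyVector = TRUE),
    error = function(e) abort(paste0("cannot parse session JSON '", path, "': ",
                                     conditionMessage(e)))
  )
  req <- c("hand_id", "label", "pixels_per_cm", "layout", "targets", "samples")
  miss <- setdiff(req, names(j))
  if (length(miss)) {
    abort(paste0("session JSON '", path, "' is missing fields: ",
                 paste(miss, collapse = ", ")))
  }
  lay <- game_layout(
    target_distance_cm = j$layout$target_distance_cm,
    target_radius_cm = j$layout$target_radius_cm,
    center_radius_cm = j$layout$center_radius_cm,
    appearance_duration_s = j$layout$appearance_duration_s %||% 3
  )
  tg <- tibble::as_tibble(j$targets)
  tg$direction <- suppressWarnings(
    ifelse(tg$direction == "CENTER", NA_integer_, as.integer(tg$direction))
  )
  tg$appearance_index <- as.integer(tg$appearance_index)
  sm <- tibble::as_tibble(j$samples)
  units <- j$units %||% "cm"
  if (identical(units, "px")) {
    sm$x <- sm$x / j$pixels_per_cm
    sm$y <- sm$y / j$pixels_per_cm
  }
  cts_session(
    hand_id = j$hand_id, label = j$label, layout = lay,
    targets = tg, samples = sm, pixels_per_cm = j$pixels_per_cm
  )
}

#' @rdname read_session_json
#' @param session A [cts_session()].
#' @export
write_session_json <- function(session, path) {
  stopifnot(inherits(session, "cts_session"))
  tg <- session$targets
  direction <- ifelse(is.na(tg$direction), "CENTER", as.character(tg$direction))
  out <- list(
    hand_id = session$hand_id,
    label = session$label,
    units = "cm",
    pixels_per_cm = session$pixels_per_cm,
    layout = list(
      target_distance_cm = session$layout$target_distance_cm,
      target_radius_cm = session$layout$target_radius_cm,
      center_radius_cm = session$layout$center_radius_cm,
      appearance_duration_s = session$layout$appearance_duration_s
    ),
    targets = data.frame(
      direction = direction,
      appearance_index = tg$appearance_index,
      t_appear = tg$t_appear,
      t_resolve = tg$t_resolve,
      outcome = tg$outcome
    ),
    samples = as.data.frame(session$samples)
  )
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
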