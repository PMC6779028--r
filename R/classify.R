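#' Classifier configuration: the hyperparameter grid and scaling policy
#'
#' The screening classifier is a two-class support vector machine whose
#' hyperparameters are tuned by grid search. The grid spans linear and
#' radial-basis kernels with log-spaced cost (and, for the radial kernel,
#' kernel width). Features are standardised to zero mean and unit variance
#' using statistics computed on training data only -- never on a held-out
#' hand -- because the raw features mix cm/s and s units whose scales would
#' otherwise dominate the margin. Grid-search ties are broken toward the
#' smaller cost, then the linear kernel, then the smaller width: the
#' simplest model wins.
#'
#' @param kernels Character subset of `c("linear", "radial")`.
#' @param costs Numeric vector of SVM cost values.
#' @param gammas Numeric vector of radial-basis widths (ignored for the
#'   linear kernel).
#' @param scale Standardise features on training folds (default `TRUE`).
#' @param class_weights Weight classes inversely to their frequency
#'   (default `FALSE`: no weighting).
#' @return An object of class `classifier_config`.
#' @export
classifier_config <- function(kernels = c("linear", "radial"),
                              costs = 2^seq(-5, 10, by = 5),
                              gammas = 2^c(-9, -5, -1),
                              scale = TRUE,
                              class_weights = FALSE) {
  kernels <- match.arg(kernels, c("linear", "radial"), several.ok = TRUE)
  stopifnot(length(costs) >= 1, all(costs > 0),
            length(gammas) >= 1 || !"radial" %in% kernels,
            all(gammas > 0), is.logical(scale), is.logical(class_weights))
  grid <- dplyr::bind_rows(
    if ("linear" %in% kernels) {
      tibble::tibble(kernel = "linear", cost = sort(costs), gamma = NA_real_)
    },
    if ("radial" %in% kernels) {
      tidyr::expand_grid(kernel = "radial", cost = sort(costs),
                         gamma = sort(gammas))
    }
  )
  # tie-break order: listed first wins on equal inner accuracy
  grid <- grid[order(grid$cost, match(grid$kernel, c("linear", "radial")),
                     grid$gamma, na.last = FALSE), ]
  structure(
    list(grid = grid, scale = scale, class_weights = class_weights),
    class = "classifier_config"
  )
}

#' @export
print.classifier_config <- function(x, ...) {
  cat(sprintf(
    "<classifier_config> %d grid points (%s), scaling %s, class weights %s\n",
    nrow(x$grid), paste(unique(x$grid$kernel), collapse = " + "),
    if (x$scale) "on" else "off",
    if (x$class_weights) "on" else "off"
  ))
  invisible(x)
}

# ---- internals -------------------------------------------------------------

.class_levels <- c("CTS", "non-CTS")

.feature_matrix <- function(table) {
  cols <- feature_cols()
  miss <- setdiff(cols, names(table))
  if (length(miss)) {
    abort(paste0("feature table is missing columns: ",
                 paste(miss, collapse = ", ")))
  }
  m <- as.matrix(table[cols])
  if (!all(is.finite(m))) abort("feature table contains non-finite values")
  m
}

.fit_svm <- function(x, y, kernel, cost, gamma, class_weights = FALSE) {
  wts <- if (class_weights) {
    n <- table(y)
    setNames(as.numeric(sum(n) / (2 * n)), names(n))
  }
  if (kernel == "linear") {
    e1071::svm(x, y, kernel = "linear", cost = cost, scale = FALSE,
               class.weights = wts)
  } else {
    e1071::svm(x, y, kernel = "radial", cost = cost, gamma = gamma,
               scale = FALSE, class.weights = wts)
  }
}

# decision value normalised so that positive means CTS
.decision_cts <- function(fit, newx) {
  pr <- predict(fit, newx, decision.values = TRUE)
  dv <- attr(pr, "decision.values")
  if (colnames(dv)[1] == "non-CTS/CTS") -dv[, 1] else dv[, 1]
}

.scale_stats <- function(x) {
  mu <- colMeans(x)
  sdev <- apply(x, 2, sd)
  sdev[sdev == 0] <- 1
  list(mu = mu, sd = sdev)
}

.apply_scale <- function(x, st) sweep(sweep(x, 2, st$mu), 2, st$sd, "/")

# leave-one-out accuracy of one grid point on (x, y); used for inner selection
.inner_loocv_accuracy <- function(x, y, kernel, cost, gamma, class_weights) {
  n <- nrow(x)
  correct <- 0L
  for (i in seq_len(n)) {
    fit <- .fit_svm(x[-i, , drop = FALSE], y[-i], kernel, cost, gamma,
                    class_weights)
    dv <- .decision_cts(fit, x[i, , drop = FALSE])
    pred <- if (dv >= 0) "CTS" else "non-CTS"
    correct <- correct + (pred == as.character(y[i]))
  }
  correct / n
}

# pick the best grid point by inner LOOCV on the training data; the grid is
# pre-ordered so which.max resolves ties toward the simplest model
.select_config <- function(x, y, config) {
  grid <- config$grid
  if (nrow(grid) == 1L) return(grid[1L, ])
  acc <- vapply(seq_len(nrow(grid)), function(g) {
    .inner_loocv_accuracy(x, y, grid$kernel[g], grid$cost[g], grid$gamma[g],
                          config$class_weights)
  }, numeric(1))
  grid[which.max(acc), ]
}

# ---- user-facing operations ------------------------------------------------

#' Screening-performance metrics from a confusion matrix
#'
#' @param tp,fn,tn,fp Confusion counts: CTS hands predicted CTS / non-CTS,
#'   and non-CTS hands predicted non-CTS / CTS.
#' @return A one-row tibble with `sensitivity = tp/(tp+fn)`,
#'   `specificity = tn/(tn+fp)` and `ppv = tp/(tp+fp)` as proportions, plus
#'   their integer-rounded percentage twins (`*_pct`) for display. `ppv` is
#'   `NA` when no hand was predicted CTS.
#' @examples
#' confusion_metrics(tp = 27, fn = 2, tn = 8, fp = 3)
#' @export
confusion_metrics <- function(tp, fn, tn, fp) {
  counts <- c(tp = tp, fn = fn, tn = tn, fp = fp)
  if (any(counts < 0) || any(counts != round(counts))) {
    abort("confusion counts must be non-negative integers")
  }
  if (tp + fn == 0) abort("no CTS hands: sensitivity undefined")
  if (tn + fp == 0) abort("no non-CTS hands: specificity undefined")
  sens <- tp / (tp + fn)
  spec <- tn / (tn + fp)
  ppv <- if (tp + fp == 0) NA_real_ else tp / (tp + fp)
  tibble::tibble(
    sensitivity = sens, specificity = spec, ppv = ppv,
    sensitivity_pct = round(100 * sens),
    specificity_pct = round(100 * spec),
    ppv_pct = if (is.na(ppv)) NA_real_ else round(100 * ppv)
  )
}

#' Leave-one-out cross-validated screening evaluation
#'
#' Each hand is held out once and predicted by an SVM trained on the
#' remaining hands; the grid search (and the feature standardisation) is
#' re-run inside every fold on the training hands only, so no information
#' about the held-out hand leaks into its prediction. Hyperparameter
#' selection within a fold uses leave-one-out on the training hands,
#' mirroring the outer validation style. A held-out hand exactly on the
#' decision boundary is called CTS: screening favours sensitivity.
#'
#' @param table A feature table ([features_to_table()]) with both labels
#'   present, at least 2 hands each.
#' @param config A [classifier_config()].
#' @param seed Integer seed (reserved for stochastic extensions; the fit,
#'   search and tie-breaking are deterministic).
#' @return An object of class `cts_screening`: per-hand LOOCV predictions
#'   with decision values and per-fold chosen hyperparameters, the confusion
#'   matrix and [confusion_metrics()]. Use [generics::tidy()] for the
#'   per-hand table and [generics::glance()] for the one-row summary.
#' @examples
#' tab <- simulate_feature_clusters(11, 29, separation = 4, seed = 1)
#' res <- loocv_evaluate(tab, classifier_config(kernels = "linear", costs = 1))
#' glance(res)
#' @export
loocv_evaluate <- function(table, config = classifier_config(), seed = 1) {
  stopifnot(inherits(config, "classifier_config"))
  x_all <- .feature_matrix(table)
  y_all <- factor(table$label, levels = .class_levels)
  if (any(is.na(y_all))) abort("labels must be 'CTS' or 'non-CTS'")
  if (any(table(y_all) < 2)) {
    abort("each class needs at least 2 hands so every training fold contains both")
  }
  n <- nrow(x_all)

  preds <- vector("list", n)
  for (i in seq_len(n)) {
    x_tr <- x_all[-i, , drop = FALSE]
    y_tr <- droplevels(y_all[-i])
    if (config$scale) {
      st <- .scale_stats(x_tr)
      x_tr <- .apply_scale(x_tr, st)
      x_te <- .apply_scale(x_all[i, , drop = FALSE], st)
    } else {
      x_te <- x_all[i, , drop = FALSE]
    }
    best <- .select_config(x_tr, y_tr, config)
    fit <- .fit_svm(x_tr, y_tr, best$kernel, best$cost, best$gamma,
                    config$class_weights)
    dv <- .decision_cts(fit, x_te)
    preds[[i]] <- tibble::tibble(
      hand_id = table$hand_id[i],
      label = as.character(y_all[i]),
      predicted = if (dv >= 0) "CTS" else "non-CTS",
      decision_value = unname(dv),
      kernel = best$kernel, cost = best$cost, gamma = best$gamma
    )
  }
  predictions <- dplyr::bind_rows(preds)

  tp <- sum(predictions$label == "CTS" & predictions$predicted == "CTS")
  fn <- sum(predictions$label == "CTS" & predictions$predicted == "non-CTS")
  tn <- sum(predictions$label == "non-CTS" & predictions$predicted == "non-CTS")
  fp <- sum(predictions$label == "non-CTS" & predictions$predicted == "CTS")

  structure(
    list(
      predictions = predictions,
      confusion = c(tp = tp, fn = fn, tn = tn, fp = fp),
      metrics = confusion_metrics(tp, fn, tn, fp),
      config = config
    ),
    class = "cts_screening"
  )
}

#' @export
print.cts_screening <- function(x, ...) {
  m <- x$metrics
  cat(sprintf(
    "<cts_screening> n = %d (LOOCV)\n  confusion: TP %d, FN %d, TN %d, FP %d\n  sensitivity %d%%, specificity %d%%, PPV %s%%\n",
    nrow(x$predictions), x$confusion["tp"], x$confusion["fn"],
    x$confusion["tn"], x$confusion["fp"],
    m$sensitivity_pct, m$specificity_pct,
    if (is.na(m$ppv_pct)) "NA" else m$ppv_pct
  ))
  invisible(x)
}

#' @rdname loocv_evaluate
#' @param x A `cts_screening` object.
#' @param ... Unused.
#' @export
tidy.cts_screening <- function(x, ...) x$predictions

#' @rdname loocv_evaluate
#' @export
glance.cts_screening <- function(x, ...) {
  dplyr::bind_cols(
    tibble::tibble(
      n = nrow(x$predictions),
      tp = unname(x$confusion["tp"]), fn = unname(x$confusion["fn"]),
      tn = unname(x$confusion["tn"]), fp = unname(x$confusion["fp"])
    ),
    x$metrics,
    tibble::tibble(
      balanced_accuracy = (x$metrics$sensitivity + x$metrics$specificity) / 2
    )
  )
}

#' Decision-value plot of a screening evaluation
#'
#' Shows each hand's signed distance to the decision boundary under LOOCV,
#' grouped by true label; hands on the wrong side of zero are the
#' misclassifications behind the sensitivity and specificity.
#'
#' @param object A `cts_screening` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.cts_screening <- function(object, ...) {
  df <- object$predictions
  ggplot2::ggplot(df, ggplot2::aes(
    x = .data$label, y = .data$decision_value,
    colour = .data$predicted
  )) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2) +
    ggplot2::geom_jitter(width = 0.15, height = 0) +
    ggplot2::labs(
      x = "true label", y = "decision value (positive = CTS)",
      colour = "predicted",
      title = "LOOCV decision values"
    ) +
    ggplot2::theme_minimal()
}

#' Train the final screening model on all hands
#'
#' Selects hyperparameters by leave-one-out grid search on the full table,
#' standardises the features, and fits the SVM on every hand. The returned
#' model screens new hands with [screen()] and round-trips through
#' [write_screening_model()] / [read_screening_model()].
#'
#' @inheritParams loocv_evaluate
#' @return An object of class `cts_model`.
#' @export
train_final <- function(table, config = classifier_config(), seed = 1) {
  stopifnot(inherits(config, "classifier_config"))
  x <- .feature_matrix(table)
  y <- factor(table$label, levels = .class_levels)
  if (any(is.na(y))) abort("labels must be 'CTS' or 'non-CTS'")
  if (any(table(y) < 2)) abort("each class needs at least 2 hands")
  st <- if (config$scale) .scale_stats(x) else list(mu = rep(0, ncol(x)),
                                                   sd = rep(1, ncol(x)))
  xs <- .apply_scale(x, st)
  best <- .select_config(xs, y, config)
  fit <- .fit_svm(xs, y, best$kernel, best$cost, best$gamma,
                  config$class_weights)
  structure(
    list(
      schema_version = 1L,
      feature_cols = feature_cols(),
      center = st$mu, scale = st$sd,
      hyperparameters = best,
      fit = fit,
      n_train = nrow(x)
    ),
    class = "cts_model"
  )
}

#' @export
print.cts_model <- function(x, ...) {
  h <- x$hyperparameters
  cat(sprintf(
    "<cts_model> SVM (%s kernel, cost %g%s) trained on %d hands\n",
    h$kernel, h$cost,
    if (is.na(h$gamma)) "" else sprintf(", gamma %g", h$gamma),
    x$n_train
  ))
  invisible(x)
}

#' Screen a hand with a trained model
#'
#' @param model A [train_final()] model.
#' @param features A `reach_features` object, a named 36-vector in canonical
#'   order, or a one-row feature table.
#' @return A one-row tibble: `label` (`"CTS"` on the boundary -- screening
#'   favours sensitivity) and `decision_value` (signed distance to the
#'   boundary, positive toward CTS).
#' @export
screen <- function(model, features) {
  stopifnot(inherits(model, "cts_model"))
  v <- if (inherits(features, "reach_features")) {
    feature_values(features)
  } else if (is.data.frame(features)) {
    if (nrow(features) != 1L) abort("screen() takes one hand at a time")
    drop(.feature_matrix(features)[1L, ])
  } else if (is.numeric(features)) {
    features
  } else {
    abort("unsupported feature input")
  }
  if (length(v) != length(model$feature_cols)) {
    abort(sprintf("expected %d features, got %d",
                  length(model$feature_cols), length(v)))
  }
  if (!is.null(names(v)) && !identical(names(v), model$feature_cols)) {
    abort("feature names do not match the canonical ordering")
  }
  if (!all(is.finite(v))) abort("features must be finite")
  xs <- (v - model$center) / model$scale
  dv <- .decision_cts(model$fit, matrix(xs, nrow = 1))
  tibble::tibble(
    label = if (dv >= 0) "CTS" else "non-CTS",
    decision_value = unname(dv)
  )
}

#' Serialise a screening model
#'
#' Writes the model as a single RDS file wrapped in a schema-versioned
#' header, so a loaded model reproduces its predictions exactly.
#'
#' @param model A `cts_model`.
#' @param path File path.
#' @return `path` invisibly; `read_screening_model()` returns the model.
#' @export
write_screening_model <- function(model, path) {
  stopifnot(inherits(model, "cts_model"))
  saveRDS(list(format = "thumbscreen_model", schema_version = 1L,
               model = model), path)
  invisible(path)
}

#' @rdname write_screening_model
#' @export
read_screening_model <- function(path) {
  if (!file.exists(path)) abort(paste0("model file not found: ", path))
  obj <- readRDS(path)
  if (!identical(obj$format, "thumbscreen_model")) {
    abort("not a thumbscreen model file")
  }
  if (!identical(obj$schema_version, 1L)) {
    abort(sprintf("unsupported model schema version %s", obj$schema_version))
  }
  obj$model
}
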