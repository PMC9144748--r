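#' Split a window dataset into training and test sets
#'
#' Partitions the windows at `train_frac` (7:3 by default). The default
#' `chronological` mode splits each recording by time — training windows
#' precede all test windows within every recording — so no test window
#' shares samples with a training window despite the 50% overlap.
#' `random` mode shuffles all windows with the given seed, mirroring the
#' common protocol that ignores overlap leakage.
#'
#' @param dataset A [make_windows()] / [bind_windows()] dataset.
#' @param train_frac Training fraction in (0, 1).
#' @param mode `"chronological"` (default) or `"random"`.
#' @param seed Integer seed for `random` mode.
#'
#' @return List with `train` and `test` window datasets.
#' @export
split_dataset <- function(dataset, train_frac = 0.7,
                          mode = c("chronological", "random"), seed = 1L) {
  mode <- match.arg(mode)
  if (!inherits(dataset, "window_dataset") || n_windows(dataset) == 0L)
    stop("split_dataset: dataset must be a non-empty window_dataset", call. = FALSE)
  if (train_frac <= 0 || train_frac >= 1)
    stop("split_dataset: train_frac must lie in (0, 1)", call. = FALSE)
  n <- n_windows(dataset)
  if (mode == "random") {
    perm <- withr::with_seed(as.integer(seed), sample.int(n))
    tr <- sort(perm[seq_len(round(n * train_frac))])
  } else {
    tr <- integer(0)
    for (rec in unique(dataset$recording)) {
      idx <- which(dataset$recording == rec)
      idx <- idx[order(dataset$window_starts[idx])]
      tr <- c(tr, idx[seq_len(round(length(idx) * train_frac))])
    }
    tr <- sort(tr)
  }
  list(train = dataset[tr], test = dataset[setdiff(seq_len(n), tr)])
}

#' Train the two-stage ensemble step counter
#'
#' Fits (i) a carrying-position classifier on all training windows
#' (features -> position) and (ii), for every position, one step-count
#' regressor per requested algorithm on that position's windows only
#' (features -> per-window step count). The `"ensemble"` regressor is the
#' weighted average of the SVM, MLP and random-forest regressors (uniform
#' weights by default) and requires those three to be trained. All models
#' internally receive the raw window samples plus three window summary
#' statistics (mean, SD, mean-crossing count).
#'
#' @param train_set Labeled training [make_windows()] dataset covering
#'   all three carrying positions.
#' @param specs List of [model_spec()]s: at most one classifier spec plus
#'   regressor specs (defaults to [default_model_specs()]).
#'
#' @return A fitted `step_counter`: fields `classifier`, `regressors`
#'   (position -> algorithm -> model), `ensemble_weights`, `config`.
#' @export
#' @seealso [count_steps()], [classify_position()], [predict_window_steps()]
train_step_counter <- function(train_set, specs = default_model_specs()) {
  if (!inherits(train_set, "window_dataset"))
    stop("train_step_counter: train_set must be a window_dataset", call. = FALSE)
  if (any(is.na(train_set$labels)))
    stop("train_step_counter: training windows must be labeled", call. = FALSE)
  stopifnot(all(vapply(specs, inherits, logical(1), "model_spec")))
  missing_pos <- setdiff(carrying_positions(), unique(train_set$positions))
  if (length(missing_pos) > 0)
    stop("train_step_counter: no training windows for position(s): ",
         paste(missing_pos, collapse = ", "), call. = FALSE)

  cls_specs <- Filter(function(s) s$role == "classifier", specs)
  reg_specs <- Filter(function(s) s$role == "regressor", specs)
  if (length(cls_specs) == 0L)
    cls_specs <- list(model_spec("random_forest", "classifier"))
  if (length(cls_specs) > 1L)
    stop("train_step_counter: supply a single classifier spec", call. = FALSE)
  if (length(reg_specs) == 0L)
    stop("train_step_counter: at least one regressor spec is required", call. = FALSE)

  ens_spec <- Filter(function(s) s$algorithm == "ensemble", reg_specs)
  base_specs <- Filter(function(s) s$algorithm != "ensemble", reg_specs)
  weights <- NULL
  if (length(ens_spec) > 0) {
    weights <- ens_spec[[1]]$hyperparams$weights
    need <- names(weights)[weights > 0]
    have <- vapply(base_specs, `[[`, character(1), "algorithm")
    if (!all(need %in% have))
      stop("train_step_counter: ensemble needs regressor specs for: ",
           paste(setdiff(need, have), collapse = ", "), call. = FALSE)
  }

  X <- augment_features(train_set$features)
  pos <- factor(train_set$positions, levels = carrying_positions())
  classifier <- fit_bank_model(cls_specs[[1]], X, pos)

  regressors <- list()
  for (p in carrying_positions()) {
    idx <- which(train_set$positions == p)
    regressors[[p]] <- list()
    for (s in base_specs)
      regressors[[p]][[s$algorithm]] <-
        fit_bank_model(s, X[idx, , drop = FALSE], train_set$labels[idx])
  }

  structure(
    list(classifier = classifier, regressors = regressors,
         ensemble_weights = weights,
         config = train_set$meta,
         specs = specs),
    class = "step_counter"
  )
}

#' @export
print.step_counter <- function(x, ...) {
  algs <- names(x$regressors[[1]])
  cat(sprintf("<step_counter> %s classifier + %d position(s) x {%s} regressors\n",
              x$classifier$algorithm, length(x$regressors),
              paste(algs, collapse = ", ")))
  if (!is.null(x$ensemble_weights))
    cat("  ensemble weights:",
        paste(sprintf("%s=%.3f", names(x$ensemble_weights), x$ensemble_weights),
              collapse = ", "), "\n")
  invisible(x)
}

check_feature_length <- function(model, features) {
  L <- model$config$window_len
  if (is.null(dim(features))) {
    if (length(features) != L)
      stop(sprintf("feature vector has %d entries, model expects %d",
                   length(features), L), call. = FALSE)
    features <- matrix(features, nrow = 1)
  } else if (ncol(features) != L) {
    stop(sprintf("feature matrix has %d columns, model expects %d",
                 ncol(features), L), call. = FALSE)
  }
  features
}

#' Classify the carrying position of windows
#'
#' @param model A fitted `step_counter`.
#' @param features One window feature vector, or a matrix with one window
#'   per row (length/width must equal the training window length).
#'
#' @return Character vector of position labels, one per window.
#' @export
classify_position <- function(model, features) {
  stopifnot(inherits(model, "step_counter"))
  X <- augment_features(check_feature_length(model, features))
  predict_bank(model$classifier, X)
}

#' Predict the step count of windows with a specific regressor
#'
#' Applies the regressor trained for `position`. `algorithm = "ensemble"`
#' returns the weighted average of the SVM, MLP and random-forest
#' predictions. Predictions are floored at 0.
#'
#' @param model A fitted `step_counter`.
#' @param features Window feature vector or matrix (one window per row).
#' @param position Carrying position whose regressor bank to use.
#' @param algorithm Regressor name, or `"ensemble"`.
#'
#' @return Numeric vector of non-negative per-window step predictions.
#' @export
predict_window_steps <- function(model, features, position,
                                 algorithm = "ensemble") {
  stopifnot(inherits(model, "step_counter"))
  if (!position %in% names(model$regressors))
    stop("predict_window_steps: unknown position: ", position, call. = FALSE)
  bank <- model$regressors[[position]]
  X <- augment_features(check_feature_length(model, features))
  if (algorithm == "ensemble") {
    w <- model$ensemble_weights
    if (is.null(w))
      stop("predict_window_steps: model was trained without an ensemble spec",
           call. = FALSE)
    preds <- vapply(names(w), function(a) {
      if (w[[a]] == 0) return(numeric(nrow(X)))
      pmax(predict_bank(bank[[a]], X), 0)
    }, numeric(nrow(X)))
    if (is.null(dim(preds))) preds <- matrix(preds, nrow = 1)
    return(pmax(as.numeric(preds %*% w), 0))
  }
  if (!algorithm %in% names(bank))
    stop("predict_window_steps: unknown algorithm: ", algorithm, call. = FALSE)
  pmax(predict_bank(bank[[algorithm]], X), 0)
}

#' Count the steps in a whole acceleration recording
#'
#' The full inference pipeline: magnitude, moving-average smoothing,
#' sliding windows, per-window position classification, then per-window
#' step regression with the regressor of the recording-level
#' majority-vote position (phone placement is fixed within a recording;
#' the majority vote suppresses isolated misclassifications — set
#' `per_window_routing = TRUE` to route each window by its own predicted
#' position instead). Overlapping window predictions are combined by a
#' coverage-corrected sum: the mean per-window step rate times the span
#' the windows cover, which reduces to `sum(pred) * stride / window_len`
#' in the interior (half the sum at 50% overlap) and to the bare
#' prediction for a single window.
#'
#' @param model A fitted `step_counter`.
#' @param accel An [accel_trace()] spanning at least one window.
#' @param algorithm Regressor to use (default `"ensemble"`).
#' @param maf_half_width Half-width of the smoothing filter applied to
#'   the magnitude before windowing.
#' @param per_window_routing Route each window by its own predicted
#'   position rather than the recording majority.
#'
#' @return List with `total` (integer step count), `position` (the
#'   majority-vote position), `position_votes` (per-window tally) and
#'   `per_window` (data frame of window starts, positions, predictions).
#' @export
# Coverage-corrected total: mean per-window step rate times the span the
# windows cover (in samples).
aggregate_window_preds <- function(preds, stride, window_len) {
  k <- length(preds)
  covered <- (k - 1) * stride + window_len
  as.integer(round(sum(preds) / k * covered / window_len))
}

count_steps <- function(model, accel, algorithm = "ensemble",
                        maf_half_width = 2L, per_window_routing = FALSE) {
  stopifnot(inherits(model, "step_counter"))
  mag <- moving_average(magnitude(accel), maf_half_width)
  wd <- make_windows(mag, events = NULL,
                     window_s = model$config$window_s,
                     overlap_frac = model$config$overlap_frac,
                     sample_rate_hz = model$config$sample_rate_hz)
  cls <- classify_position(model, wd$features)
  votes <- table(factor(cls, levels = carrying_positions()))
  majority <- names(votes)[which.max(votes)]
  route <- if (per_window_routing) cls else rep(majority, length(cls))
  preds <- numeric(length(cls))
  for (p in unique(route)) {
    idx <- which(route == p)
    preds[idx] <- predict_window_steps(model, wd$features[idx, , drop = FALSE],
                                       p, algorithm)
  }
  list(total = aggregate_window_preds(preds, model$config$stride,
                                      model$config$window_len),
       position = majority,
       position_votes = votes,
       per_window = data.frame(window_start_ms = wd$window_starts,
                               position = route, predicted_steps = preds))
}
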