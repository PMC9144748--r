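#' Step-count accuracy
#'
#' `(1 - |ne - nr| / nr) * 100`, the relative-error-based accuracy used
#' to score estimated against real step counts. The value is 100 for a
#' perfect estimate, 0 when the absolute error equals the real count, and
#' goes negative (unclamped) when the estimate exceeds twice the real
#' count. Vectorised over `ne`/`nr`.
#'
#' @param ne Estimated step count(s), >= 0.
#' @param nr Real step count(s), > 0.
#'
#' @return Accuracy in percent.
#' @export
#' @examples
#' step_accuracy(97, 100)  # 97
step_accuracy <- function(ne, nr) {
  if (any(nr <= 0))
    stop("step_accuracy: real step count nr must be positive", call. = FALSE)
  (1 - abs(ne - nr) / nr) * 100
}

#' Classification accuracy
#'
#' Percentage of predictions matching the truth.
#'
#' @param predicted,truth Equal-length vectors of position labels.
#' @return Accuracy in percent.
#' @export
classification_accuracy <- function(predicted, truth) {
  if (length(predicted) != length(truth) || length(truth) == 0L)
    stop("classification_accuracy: predicted and truth must be non-empty and of equal length",
         call. = FALSE)
  100 * mean(as.character(predicted) == as.character(truth))
}

#' Build a position-by-algorithm accuracy report
#'
#' Aggregates per-recording results into the standard report table: one
#' row per carrying position, one column per algorithm, each cell the
#' unweighted mean of that cell's per-recording step-count accuracies,
#' plus marginal averages (row average across algorithms, column average
#' across positions). Cells are stored at full precision; rounding to one
#' decimal happens only when the report is formatted.
#'
#' @param results Data frame with columns `position`, `algorithm` and
#'   either `accuracy` (percent) or `ne` and `nr` (counts, from which
#'   [step_accuracy()] is computed). One row per recording evaluation.
#'
#' @return A list of class `accuracy_report` with `per_cell` matrix,
#'   `row_avgs`, `col_avgs` and `n_recordings`.
#' @export
build_report <- function(results) {
  results <- as.data.frame(results)
  if (nrow(results) == 0L)
    stop("build_report: results must be non-empty", call. = FALSE)
  if (!all(c("position", "algorithm") %in% names(results)))
    stop("build_report: results need position and algorithm columns", call. = FALSE)
  if (!"accuracy" %in% names(results)) {
    if (!all(c("ne", "nr") %in% names(results)))
      stop("build_report: results need either an accuracy column or ne and nr",
           call. = FALSE)
    results$accuracy <- step_accuracy(results$ne, results$nr)
  }
  pos_lev <- intersect(carrying_positions(), unique(results$position))
  if (length(pos_lev) == 0L) pos_lev <- unique(results$position)
  alg_lev <- unique(results$algorithm)
  per_cell <- tapply(results$accuracy,
                     list(factor(results$position, levels = pos_lev),
                          factor(results$algorithm, levels = alg_lev)),
                     mean)
  structure(
    list(per_cell = per_cell,
         row_avgs = rowMeans(per_cell, na.rm = TRUE),
         col_avgs = colMeans(per_cell, na.rm = TRUE),
         n_recordings = nrow(results)),
    class = "accuracy_report"
  )
}

#' @export
format.accuracy_report <- function(x, ...) {
  tab <- cbind(x$per_cell, Average = x$row_avgs)
  tab <- rbind(tab, Average = c(x$col_avgs, NA))
  cells <- ifelse(is.na(tab), "", sprintf("%.1f", tab))
  dim(cells) <- dim(tab)
  df <- data.frame(position = rownames(tab), cells, check.names = FALSE)
  names(df) <- c("position", colnames(tab))
  paste(c("Mean step-count accuracies (%)",
          utils::capture.output(print(df, row.names = FALSE)),
          "Note: accuracy is unclamped and can be negative when ne > 2 * nr."),
        collapse = "\n")
}

#' @export
print.accuracy_report <- function(x, ...) {
  cat(format(x), "\n")
  invisible(x)
}

#' Report as a data frame
#'
#' @param x An `accuracy_report`.
#' @param row.names,optional,... Passed over (unused).
#' @return Data frame with the per-cell accuracies and marginal averages,
#'   full precision.
#' @export
as.data.frame.accuracy_report <- function(x, row.names = NULL, optional = FALSE, ...) {
  tab <- cbind(x$per_cell, Average = x$row_avgs)
  tab <- rbind(tab, Average = c(x$col_avgs, NA))
  df <- as.data.frame(tab)
  df <- cbind(position = rownames(tab), df)
  rownames(df) <- NULL
  df
}
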