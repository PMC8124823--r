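#' Confusion matrix with the experimental (elderly) group as positive class
#'
#' Cross-tabulates predicted against true group labels. The experimental
#' (elderly) group is the target class throughout the package, so `tp` counts
#' recordings correctly called experimental and `tn` recordings correctly
#' called control.
#'
#' @param predictions character or factor vector of predicted labels, each
#'   `"control"` or `"experimental"`.
#' @param truth vector of true labels, same length and label set.
#' @return an object of class `confusion_matrix`: a list with integer counts
#'   `tp`, `fn`, `fp`, `tn`.
#' @export
confusion <- function(predictions, truth) {
  predictions <- as.character(predictions)
  truth <- as.character(truth)
  if (length(predictions) != length(truth))
    stop("predictions and truth differ in length (", length(predictions),
         " vs ", length(truth), ")")
  if (length(truth) < 1L) stop("need at least one observation")
  ok <- c("control", "experimental")
  bad <- setdiff(unique(c(predictions, truth)), ok)
  if (length(bad))
    stop("unknown group label(s): ", paste(bad, collapse = ", "))
  cm <- list(
    tp = sum(predictions == "experimental" & truth == "experimental"),
    fn = sum(predictions == "control" & truth == "experimental"),
    fp = sum(predictions == "experimental" & truth == "control"),
    tn = sum(predictions == "control" & truth == "control")
  )
  cm <- lapply(cm, as.integer)
  structure(cm, class = "confusion_matrix")
}

#' Build a confusion matrix from raw counts
#'
#' @param tp,fn,fp,tn non-negative integer counts; positive class is the
#'   experimental (elderly) group.
#' @return a `confusion_matrix` object.
#' @export
confusion_counts <- function(tp, fn, fp, tn) {
  counts <- c(tp = tp, fn = fn, fp = fp, tn = tn)
  if (any(!is.finite(counts)) || any(counts < 0) ||
      any(counts != round(counts)))
    stop("confusion counts must be non-negative integers")
  if (sum(counts) < 1) stop("confusion matrix must contain at least one case")
  structure(as.list(as.integer(counts)), names = names(counts),
            class = "confusion_matrix")
}

#' @export
print.confusion_matrix <- function(x, ...) {
  m <- matrix(c(x$tp, x$fp, x$fn, x$tn), 2, 2,
              dimnames = list(predicted = c("experimental", "control"),
                              truth = c("experimental", "control")))
  cat("Confusion matrix (positive class: experimental)\n")
  print(m)
  invisible(x)
}

#' Six classification indices from a 2x2 confusion matrix
#'
#' Computes accuracy, sensitivity, specificity, positive and negative
#' predictive value, and Cohen's kappa, with the experimental group as the
#' positive class:
#' \deqn{\kappa = (p_o - p_e) / (1 - p_e)}
#' where \eqn{p_o} is the observed agreement (accuracy) and
#' \eqn{p_e = [(tp+fp)(tp+fn) + (fn+tn)(fp+tn)] / N^2} the chance agreement.
#'
#' Ratios with a zero denominator (e.g. PPV when nothing is predicted
#' positive) are reported as `NaN` and flagged via the `undefined` attribute,
#' never silently coerced to zero — a silent zero would corrupt
#' kappa-based rankings downstream.
#'
#' @param cm a `confusion_matrix`.
#' @return a named numeric vector of class `metric_set` with elements
#'   `accuracy`, `sensitivity`, `specificity`, `ppv`, `npv`, `kappa`, and an
#'   attribute `undefined` naming any metric whose denominator was zero.
#' @export
metric_set <- function(cm) {
  stopifnot(inherits(cm, "confusion_matrix"))
  tp <- cm$tp; fn <- cm$fn; fp <- cm$fp; tn <- cm$tn
  n <- tp + fn + fp + tn
  if (n < 1) stop("empty confusion matrix")
  ratio <- function(num, den) if (den == 0) NaN else num / den
  po <- (tp + tn) / n
  pe <- ((tp + fp) * (tp + fn) + (fn + tn) * (fp + tn)) / n^2
  out <- c(
    accuracy    = po,
    sensitivity = ratio(tp, tp + fn),
    specificity = ratio(tn, tn + fp),
    ppv         = ratio(tp, tp + fp),
    npv         = ratio(tn, tn + fn),
    kappa       = if (pe == 1) NaN else (po - pe) / (1 - pe)
  )
  attr(out, "undefined") <- names(out)[is.nan(out)]
  class(out) <- c("metric_set", class(out))
  out
}

#' @export
print.metric_set <- function(x, digits = 4, ...) {
  v <- format(round(unclass(x), digits), nsmall = 2)
  cat(paste(sprintf("%-12s %s", names(x), v), collapse = "\n"), "\n")
  if (length(attr(x, "undefined")))
    cat("undefined (zero denominator):",
        paste(attr(x, "undefined"), collapse = ", "), "\n")
  invisible(x)
}

#' Filter and rank model results by Cohen's kappa
#'
#' Keeps models meeting the accuracy and kappa thresholds and sorts the
#' survivors in ascending order of kappa (ties broken by ascending accuracy,
#' then model id), the ordering used in the reported model tables.
#'
#' @param results a `jnp_grid` object or the data frame from
#'   [as.data.frame.jnp_grid()].
#' @param min_accuracy,min_kappa inclusive thresholds; defaults mirror the
#'   reported selection (accuracy >= 0.95, kappa >= 0.88). Use `-Inf` to keep
#'   everything.
#' @return a data frame with columns `model`, `epoch`, `backend`, `learner`,
#'   `accuracy`, `sensitivity`, `specificity`, `ppv`, `npv`, `kappa`. Empty
#'   (zero rows, full header) when nothing survives the filter.
#' @export
rank_models <- function(results, min_accuracy = 0.95, min_kappa = 0.88) {
  df <- if (inherits(results, "jnp_grid")) as.data.frame(results) else
    as.data.frame(results)
  need <- c("model", "epoch", "backend", "learner", "accuracy", "sensitivity",
            "specificity", "ppv", "npv", "kappa")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols))
    stop("results lack column(s): ", paste(missing_cols, collapse = ", "))
  if (nrow(df) == 0) stop("no results to rank")
  keep <- !is.na(df$accuracy) & !is.na(df$kappa) &
    df$accuracy >= min_accuracy & df$kappa >= min_kappa
  out <- df[keep, need, drop = FALSE]
  out <- out[order(out$kappa, out$accuracy, out$model), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Long-form radar-plot data for a ranked report table
#'
#' One row per (model, metric) pair, suitable for drawing a six-axis radar
#' plot in any plotting tool (the package exports the data only).
#'
#' @param ranked a data frame from [rank_models()].
#' @return data frame with columns `model`, `metric`, `value`.
#' @export
radar_data <- function(ranked) {
  metrics <- c("accuracy", "sensitivity", "specificity", "ppv", "npv", "kappa")
  if (nrow(ranked) == 0)
    return(data.frame(model = character(), metric = character(),
                      value = numeric()))
  data.frame(
    model = rep(ranked$model, each = length(metrics)),
    metric = rep(metrics, times = nrow(ranked)),
    value = as.numeric(t(as.matrix(ranked[, metrics]))),
    stringsAsFactors = FALSE
  )
}

#' Write a ranked report as CSV and JSON
#'
#' The CSV mirrors the tabulated report layout (`Model Epoch CNN Learner
#' Accuracy Sensitivity Specificity PPV NPV Kappa`) with metrics printed to
#' two decimals; the JSON keeps full precision and embeds the radar-plot
#' block.
#'
#' @param ranked data frame from [rank_models()].
#' @param csv_path,json_path output paths; either may be `NULL` to skip.
#' @param radar_csv_path optional path for long-form radar data CSV.
#' @return invisibly, the list written to JSON.
#' @export
export_report <- function(ranked, csv_path = NULL, json_path = NULL,
                          radar_csv_path = NULL) {
  metrics <- c("accuracy", "sensitivity", "specificity", "ppv", "npv", "kappa")
  if (!is.null(csv_path)) {
    disp <- ranked
    for (m in metrics) disp[[m]] <- sprintf("%.2f", disp[[m]])
    names(disp) <- c("Model", "Epoch", "CNN", "Learner", "Accuracy",
                     "Sensitivity", "Specificity", "PPV", "NPV", "Kappa")
    write.csv(disp, csv_path, row.names = FALSE, quote = FALSE, na = "NA")
  }
  payload <- list(models = ranked, radar = radar_data(ranked))
  if (!is.null(json_path))
    jsonlite::write_json(payload, json_path, dataframe = "rows",
                         auto_unbox = TRUE, digits = NA, na = "string")
  if (!is.null(radar_csv_path))
    write.csv(radar_data(ranked), radar_csv_path, row.names = FALSE,
              quote = FALSE)
  invisible(payload)
}
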