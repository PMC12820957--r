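#' Confusion-matrix metrics for a binary classification
#'
#' Compares predicted against true `"positive"`/`"negative"` labels on the
#' same ligand set and derives the confusion counts together with the
#' Matthews correlation coefficient (MCC), balanced accuracy (BAC) and
#' per-class precision/recall/F1. MCC is defined as 0 when any of its four
#' denominator factors is 0 (the standard convention, keeping the metric
#' total); BAC is the mean of the two class recalls.
#'
#' @param data A data frame holding both label columns, or a named character
#'   vector of predicted labels (then `truth` must be a named vector too).
#' @param truth,predicted Column names in `data` (defaults `"truth"`,
#'   `"predicted"`), or the named truth vector in the vector interface.
#' @return A one-row tibble of class `classification_metrics` with columns
#'   `tp`, `fp`, `fn`, `tn`, `mcc`, `bac`, and precision/recall/F1 for the
#'   positive and negative class.
#' @examples
#' classification_metrics(
#'   data.frame(truth = c("positive", "negative"),
#'              predicted = c("positive", "positive"))
#' )
#' @export
classification_metrics <- function(data, truth = "truth", predicted = "predicted") {
  if (is.data.frame(data)) {
    t_lab <- as.character(data[[truth]])
    p_lab <- as.character(data[[predicted]])
  } else {
    p_lab <- as.character(data)
    t_lab <- as.character(truth)
    if (!is.null(names(data)) && !is.null(names(truth))) {
      common <- intersect(names(data), names(truth))
      if (length(common) != length(data) || length(common) != length(truth)) {
        abort("Predicted and truth labels must cover the same ligand set.")
      }
      p_lab <- as.character(data[common])
      t_lab <- as.character(truth[common])
    }
  }
  ok <- c("positive", "negative")
  bad <- setdiff(unique(c(t_lab, p_lab)), ok)
  if (length(bad) > 0) {
    abort(paste0("Labels must be 'positive' or 'negative'; got: ",
                 paste(bad, collapse = ", ")))
  }
  if (length(t_lab) != length(p_lab)) {
    abort("Predicted and truth labels must have equal length.")
  }
  metrics_from_counts(
    tp = sum(p_lab == "positive" & t_lab == "positive"),
    fp = sum(p_lab == "positive" & t_lab == "negative"),
    fn = sum(p_lab == "negative" & t_lab == "positive"),
    tn = sum(p_lab == "negative" & t_lab == "negative")
  )
}

#' @rdname classification_metrics
#' @param tp,fp,fn,tn Nonnegative integer confusion counts (true/false
#'   positives/negatives), e.g. read off a published confusion matrix.
#' @export
metrics_from_counts <- function(tp, fp, fn, tn) {
  counts <- c(tp = tp, fp = fp, fn = fn, tn = tn)
  if (any(counts < 0) || any(counts != round(counts))) {
    abort("Confusion counts must be nonnegative integers.")
  }
  denom <- prod(sqrt(c(tp + fp, tp + fn, tn + fp, tn + fn)))
  mcc <- if (denom == 0) 0 else (tp * tn - fp * fn) / denom
  recall_pos <- safe_div(tp, tp + fn)
  recall_neg <- safe_div(tn, tn + fp)
  precision_pos <- safe_div(tp, tp + fp)
  precision_neg <- safe_div(tn, tn + fn)
  out <- tibble(
    tp = as.integer(tp), fp = as.integer(fp),
    fn = as.integer(fn), tn = as.integer(tn),
    mcc = mcc,
    bac = (recall_pos + recall_neg) / 2,
    precision_positive = precision_pos,
    recall_positive = recall_pos,
    f1_positive = f1_score(precision_pos, recall_pos),
    precision_negative = precision_neg,
    recall_negative = recall_neg,
    f1_negative = f1_score(precision_neg, recall_neg)
  )
  class(out) <- c("classification_metrics", class(out))
  out
}

safe_div <- function(num, den) if (den == 0) NA_real_ else num / den

f1_score <- function(p, r) {
  if (is.na(p) || is.na(r) || p + r == 0) return(NA_real_)
  2 * p * r / (p + r)
}

#' @exportS3Method generics::glance
glance.classification_metrics <- function(x, ...) {
  tibble(n = x$tp + x$fp + x$fn + x$tn, mcc = x$mcc, bac = x$bac)
}

#' Serialize metrics or a threshold model to JSON
#'
#' Metrics are written with integer counts plus both 3-decimal rounded and
#' full-precision values; threshold models carry their crossing audit list.
#'
#' @param x A `classification_metrics` row or `threshold_model`.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_metrics_json <- function(x, path) {
  if (inherits(x, "threshold_model")) {
    obj <- list(
      function_name = x$function_name, threshold = x$threshold,
      positive_side = x$positive_side, domain = x$domain,
      bandwidth = as.list(x$bandwidth),
      crossings = x$crossings
    )
  } else {
    obj <- as.list(x)
    for (m in c("mcc", "bac")) obj[[paste0(m, "_rounded")]] <- round(obj[[m]], 3)
  }
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       na = "null")
  invisible(path)
}
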