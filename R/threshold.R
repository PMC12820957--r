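#' Gaussian kernel density estimate on a fixed grid
#'
#' Smooths a 1-D sample (scores or ranks) with a Gaussian kernel on a
#' uniform grid spanning `[min - 3h, max + 3h]`. Bandwidth rules: `"scott"`
#' (default) uses `h = s * n^(-1/5)` with `s` the sample standard deviation;
#' `"silverman"` uses `h = 0.9 * min(s, IQR/1.34) * n^(-1/5)`; `"fixed"`
#' uses `fixed_h` verbatim.
#'
#' @param values Numeric vector with at least 2 distinct finite values.
#' @param bandwidth_rule One of `"scott"`, `"silverman"`, `"fixed"`.
#' @param fixed_h Bandwidth when `bandwidth_rule = "fixed"`.
#' @param grid_points Number of grid points (default 512).
#' @return A tibble with columns `grid` and `density`, plus attributes
#'   `bandwidth` and `n_samples`. The trapezoid integral of the curve is 1
#'   up to grid discretisation.
#' @export
kde_density <- function(values, bandwidth_rule = c("scott", "silverman", "fixed"),
                        fixed_h = NULL, grid_points = 512) {
  bandwidth_rule <- rlang::arg_match(bandwidth_rule)
  values <- values[is.finite(values)]
  h <- kde_bandwidth(values, bandwidth_rule, fixed_h)
  d <- density(values, bw = h, kernel = "gaussian",
               from = min(values) - 3 * h, to = max(values) + 3 * h,
               n = grid_points)
  out <- tibble(grid = d$x, density = d$y)
  attr(out, "bandwidth") <- h
  attr(out, "n_samples") <- length(values)
  out
}

kde_bandwidth <- function(values, bandwidth_rule, fixed_h) {
  if (length(values) < 2 || length(unique(values)) < 2) {
    abort("KDE requires at least 2 distinct finite values (degenerate bandwidth).")
  }
  n <- length(values)
  s <- sd(values)
  h <- switch(bandwidth_rule,
    scott = s * n^(-1 / 5),
    silverman = 0.9 * min(s, stats::IQR(values) / 1.34) * n^(-1 / 5),
    fixed = {
      if (is.null(fixed_h) || !is.numeric(fixed_h) || fixed_h <= 0) {
        abort("fixed_h must be a positive number when bandwidth_rule = 'fixed'.")
      }
      fixed_h
    }
  )
  if (!is.finite(h) || h <= 0) abort("Computed bandwidth is not positive.")
  h
}

#' KDE-intersection decision threshold between two classes
#'
#' Estimates the score densities of a positive class (e.g. inhibitors of
#' the docked target) and a negative class (everything else) with Gaussian
#' KDEs on a shared grid and places the decision boundary where the two
#' curves cross. Among all sign changes of `f_pos - f_neg`, the crossing
#' lying between the two class medians is preferred (that is the boundary a
#' reader takes from a two-class KDE plot); if none lies there, the
#' crossing nearest the midpoint of the medians is used. All crossings are
#' retained in the model for audit. The crossing abscissa is refined by
#' linear interpolation between grid points, and `positive_side` records on
#' which side of the threshold the positive density dominates.
#'
#' @param pos_values,neg_values Numeric vectors (>= 2 distinct values each).
#' @param bandwidth_rule,fixed_h,grid_points As in [kde_density()].
#' @param function_name Optional scoring-function label stored in the model.
#' @param domain `"score"` (default) or `"rank"`, recording the units the
#'   threshold lives in.
#' @return A `threshold_model` object: a list with `function_name`,
#'   `threshold`, `positive_side` (`"below"` or `"above"`), `domain`,
#'   `bandwidth` (per class), `n_pos`, `n_neg` and a `crossings` tibble of
#'   every sign change found. Errors with "no intersection" when the curves
#'   never cross on the grid.
#' @seealso [classify_by_threshold()], [threshold_model()]
#' @export
intersection_threshold <- function(pos_values, neg_values,
                                   bandwidth_rule = c("scott", "silverman", "fixed"),
                                   fixed_h = NULL, grid_points = 512,
                                   function_name = NULL, domain = c("score", "rank")) {
  bandwidth_rule <- rlang::arg_match(bandwidth_rule)
  domain <- rlang::arg_match(domain)
  pos_values <- pos_values[is.finite(pos_values)]
  neg_values <- neg_values[is.finite(neg_values)]
  h_pos <- kde_bandwidth(pos_values, bandwidth_rule, fixed_h)
  h_neg <- kde_bandwidth(neg_values, bandwidth_rule, fixed_h)

  h_max <- max(h_pos, h_neg)
  lo <- min(pos_values, neg_values) - 3 * h_max
  hi <- max(pos_values, neg_values) + 3 * h_max
  f_pos <- density(pos_values, bw = h_pos, from = lo, to = hi, n = grid_points)
  f_neg <- density(neg_values, bw = h_neg, from = lo, to = hi, n = grid_points)
  x <- f_pos$x
  dif <- f_pos$y - f_neg$y

  crossings <- find_sign_changes(x, dif)
  if (nrow(crossings) == 0) {
    abort("no intersection: the class density curves never cross on the grid.")
  }

  med_lo <- min(median(pos_values), median(neg_values))
  med_hi <- max(median(pos_values), median(neg_values))
  mid <- (med_lo + med_hi) / 2
  between <- crossings$threshold >= med_lo & crossings$threshold <= med_hi
  candidates <- if (any(between)) crossings[between, ] else crossings
  chosen <- candidates[which.min(abs(candidates$threshold - mid)), ]

  threshold_model(
    threshold = chosen$threshold,
    positive_side = chosen$positive_side,
    function_name = function_name,
    domain = domain,
    bandwidth = c(pos = h_pos, neg = h_neg),
    n_pos = length(pos_values),
    n_neg = length(neg_values),
    crossings = crossings
  )
}

# Sign changes of dif on grid x; linear interpolation locates each root and
# the sign of dif to the left determines which side the positive class owns.
find_sign_changes <- function(x, dif) {
  s <- sign(dif)
  idx <- which(s[-length(s)] * s[-1] < 0 | (s[-length(s)] != 0 & s[-1] == 0))
  if (length(idx) == 0) {
    return(tibble(threshold = numeric(), positive_side = character()))
  }
  thr <- purrr::map_dbl(idx, function(i) {
    x[i] - dif[i] * (x[i + 1] - x[i]) / (dif[i + 1] - dif[i])
  })
  side <- ifelse(s[idx] > 0, "below", "above")
  tibble(threshold = thr, positive_side = side)
}

#' Construct a threshold model directly
#'
#' Builds the decision model used by [classify_by_threshold()] from known
#' quantities — for instance a published score cutoff — without running the
#' KDE machinery.
#'
#' @param threshold Numeric decision boundary.
#' @param positive_side `"below"` if scores strictly below the threshold are
#'   called positive, `"above"` otherwise.
#' @param function_name Optional scoring-function label.
#' @param domain `"score"` or `"rank"`.
#' @param bandwidth,n_pos,n_neg,crossings Optional provenance fields filled
#'   by [intersection_threshold()].
#' @return A `threshold_model` object.
#' @examples
#' threshold_model(-3170.75, "below", function_name = "glide_ifdscore")
#' @export
threshold_model <- function(threshold, positive_side = c("below", "above"),
                            function_name = NULL, domain = c("score", "rank"),
                            bandwidth = NULL, n_pos = NA_integer_,
                            n_neg = NA_integer_, crossings = NULL) {
  positive_side <- rlang::arg_match(positive_side)
  domain <- rlang::arg_match(domain)
  stopifnot(is.numeric(threshold), length(threshold) == 1)
  structure(
    list(function_name = function_name, threshold = unname(threshold),
         positive_side = positive_side, domain = domain,
         bandwidth = bandwidth, n_pos = n_pos, n_neg = n_neg,
         crossings = crossings %||%
           tibble(threshold = unname(threshold), positive_side = positive_side)),
    class = "threshold_model"
  )
}

#' @exportS3Method base::print
print.threshold_model <- function(x, ...) {
  cat("<threshold_model>", if (!is.null(x$function_name)) x$function_name else "",
      "\n  threshold:", format(x$threshold),
      paste0("(", x$domain, " units)"),
      "\n  positive side:", x$positive_side,
      "\n  crossings found:", nrow(x$crossings), "\n")
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.threshold_model <- function(x, ...) {
  tibble(
    function_name = x$function_name %||% NA_character_,
    threshold = x$threshold, positive_side = x$positive_side,
    domain = x$domain, n_pos = x$n_pos, n_neg = x$n_neg,
    n_crossings = nrow(x$crossings)
  )
}

#' Classify ligands against a score threshold
#'
#' Applies a [threshold_model()]: a ligand is `"positive"` when its value
#' lies strictly on the model's positive side, `"negative"` otherwise — a
#' value exactly on the threshold is negative (the positive rule is a
#' strict inequality). Ligands with missing scores are labeled negative
#' (a failed docking cannot exhibit favorable binding evidence) and listed
#' in a warning.
#'
#' @param data A data frame with a `ligand_id` column and a score column,
#'   or a named numeric vector.
#' @param model A `threshold_model`.
#' @param score_col Name of the score column when `data` is a data frame;
#'   defaults to the single non-`ligand_id` column.
#' @return A tibble `ligand_id`, `score`, `label`.
#' @export
classify_by_threshold <- function(data, model, score_col = NULL) {
  stopifnot(inherits(model, "threshold_model"))
  if (is.data.frame(data)) {
    if (is.null(score_col)) {
      cand <- setdiff(names(data), "ligand_id")
      if (length(cand) != 1) {
        abort("Specify score_col: multiple candidate score columns present.")
      }
      score_col <- cand
    }
    scores <- setNames(data[[score_col]], data$ligand_id)
  } else {
    scores <- data
  }
  s <- as.numeric(scores)
  pos <- if (model$positive_side == "below") s < model$threshold else s > model$threshold
  label <- ifelse(is.na(s), "negative", ifelse(pos, "positive", "negative"))
  if (anyNA(s)) {
    warn(paste0("Missing score(s) labeled negative: ",
                paste(names(scores)[is.na(s)], collapse = ", ")))
  }
  tibble(ligand_id = names(scores), score = s, label = label)
}
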