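pair_vectors <- function(data, x, y, x_quo, y_quo) {
  if (is.data.frame(data)) {
    xv <- dplyr::pull(data, !!x_quo)
    yv <- dplyr::pull(data, !!y_quo)
    ids <- if ("ligand_id" %in% names(data)) data$ligand_id else
      as.character(seq_len(nrow(data)))
  } else {
    common <- intersect(names(data), names(x))
    dropped <- setdiff(union(names(data), names(x)), common)
    if (length(dropped) > 0) {
      inform(paste0("Ligand(s) without a pair dropped: ",
                    paste(dropped, collapse = ", ")))
    }
    xv <- as.numeric(data[common])
    yv <- as.numeric(x[common])
    ids <- common
  }
  keep <- is.finite(xv) & is.finite(yv)
  if (any(!keep)) {
    inform(paste0("Incomplete pair(s) dropped: ",
                  paste(ids[!keep], collapse = ", ")))
  }
  list(x = xv[keep], y = yv[keep], ids = ids[keep])
}

check_pairs <- function(p) {
  if (length(p$x) < 3) abort("At least 3 paired observations are required.")
  if (sd(p$x) == 0 || sd(p$y) == 0) {
    abort("Zero variance in one of the vectors; correlation undefined.")
  }
  p
}

#' Rank and linear correlation between scores and activities
#'
#' Computes the Spearman rank correlation (Pearson on average-tie ranks)
#' and the Pearson product-moment correlation between two paired vectors —
#' typically a docking score or consensus rank against experimental pIC50.
#' Pairs are restricted to complete cases; dropped ligands are reported.
#' Sign bookkeeping is left to the caller: an ECR-like score correlates
#' positively with potency, an aggregated rank negatively (low rank =
#' potent).
#'
#' @param data A data frame containing both variables (with an optional
#'   `ligand_id` column), or a named numeric vector.
#' @param x,y Column names (unquoted) when `data` is a data frame; when
#'   `data` is a named vector, `x` is the second named vector and pairing
#'   is by name.
#' @return A one-row tibble `n`, `spearman_rho`, `pearson_r`.
#' @examples
#' rank_correlation(data.frame(a = 1:5, b = c(2, 1, 4, 3, 5)), a, b)
#' @export
rank_correlation <- function(data, x, y = NULL) {
  p <- check_pairs(pair_vectors(data, x, y, rlang::enquo(x), rlang::enquo(y)))
  tibble(
    n = length(p$x),
    spearman_rho = cor(p$x, p$y, method = "spearman"),
    pearson_r = cor(p$x, p$y, method = "pearson")
  )
}

#' Ordinary least-squares summary with 95% confidence band
#'
#' Fits `y ~ x` by least squares and evaluates the fitted line plus the
#' 95% confidence band for the conditional mean (t-distribution, n - 2
#' degrees of freedom) on a uniform abscissa grid — the quantities drawn in
#' a score-versus-pIC50 regression plot.
#'
#' @inheritParams rank_correlation
#' @param grid_points Number of abscissae for the band (default 100).
#' @return An `ols_report` object with fields `n`, `slope`, `intercept`,
#'   `pearson_r`, `spearman_rho`, `band` (tibble `grid`, `fit`, `lower`,
#'   `upper`), `points` (the paired data) and the underlying `lm` fit.
#'   Supports [tidy()], [glance()] and [autoplot()].
#' @export
ols_summary <- function(data, x, y = NULL, grid_points = 100) {
  p <- check_pairs(pair_vectors(data, x, y, rlang::enquo(x), rlang::enquo(y)))
  df <- data.frame(x = p$x, y = p$y)
  fit <- lm(y ~ x, data = df)
  grid <- seq(min(p$x), max(p$x), length.out = grid_points)
  pred <- predict(fit, newdata = data.frame(x = grid),
                  interval = "confidence", level = 0.95)
  structure(
    list(
      n = length(p$x),
      slope = unname(stats::coef(fit)[2]),
      intercept = unname(stats::coef(fit)[1]),
      pearson_r = cor(p$x, p$y),
      spearman_rho = cor(p$x, p$y, method = "spearman"),
      band = tibble(grid = grid, fit = pred[, "fit"],
                    lower = pred[, "lwr"], upper = pred[, "upr"]),
      points = tibble(ligand_id = p$ids, x = p$x, y = p$y),
      model = fit
    ),
    class = "ols_report"
  )
}

#' @exportS3Method base::print
print.ols_report <- function(x, ...) {
  cat("<ols_report> n =", x$n,
      "\n  fit: y =", format(x$slope, digits = 4), "* x +",
      format(x$intercept, digits = 4),
      "\n  pearson_r =", format(x$pearson_r, digits = 3),
      " spearman_rho =", format(x$spearman_rho, digits = 3), "\n")
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.ols_report <- function(x, ...) {
  out <- as_tibble(summary(x$model)$coefficients, rownames = "term")
  names(out) <- c("term", "estimate", "std.error", "statistic", "p.value")
  out$term <- c("(Intercept)", "x")
  out
}

#' @exportS3Method generics::glance
glance.ols_report <- function(x, ...) {
  tibble(n = x$n, slope = x$slope, intercept = x$intercept,
         pearson_r = x$pearson_r, spearman_rho = x$spearman_rho,
         r.squared = summary(x$model)$r.squared)
}

#' @exportS3Method ggplot2::autoplot
autoplot.ols_report <- function(object, xlab = "score", ylab = "pIC50", ...) {
  ggplot2::ggplot(object$points, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_ribbon(
      data = object$band,
      ggplot2::aes(x = .data$grid, ymin = .data$lower, ymax = .data$upper),
      inherit.aes = FALSE, fill = "orange", alpha = 0.25
    ) +
    ggplot2::geom_line(
      data = object$band,
      ggplot2::aes(x = .data$grid, y = .data$fit),
      inherit.aes = FALSE, colour = "orange"
    ) +
    ggplot2::geom_point() +
    ggplot2::labs(x = xlab, y = ylab) +
    ggplot2::theme_minimal()
}

#' Write regression-band data for external plotting
#'
#' @param report An `ols_report`.
#' @param path Output CSV path (columns `grid`, `fit`, `lower`, `upper`).
#' @return `path`, invisibly.
#' @export
write_regression_csv <- function(report, path) {
  readr::write_csv(report$band, path)
  invisible(path)
}
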