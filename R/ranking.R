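#' Direction-aware relative ranks of docking scores
#'
#' Docking scores from different programs live on incompatible scales and
#' depend on protein size, so consensus schemes operate on relative ranks
#' instead. Per scoring function, rank 1 goes to the most favorable score
#' under that function's direction (lowest score for `lower_is_better`,
#' highest for `higher_is_better`); tied scores receive average (fractional)
#' ranks. A missing score is handled by `missing_policy`: `"worst_rank"`
#' assigns rank `n_ranked + 1` (a failed docking must not be rewarded),
#' `"omit"` drops the (ligand, function) pair.
#'
#' @param table Score table tibble (`ligand_id` + one column per function),
#'   e.g. from [read_score_table()] or [generate_study()].
#' @param specs Scoring-function metadata; every score column needs a
#'   declared direction.
#' @param missing_policy `"worst_rank"` (default) or `"omit"`.
#' @return A long tibble with columns `ligand_id`, `function_name`, `rank`,
#'   `n_ranked` (ligands with observed scores for that function). The
#'   `target_id` attribute of `table` is carried over.
#' @examples
#' specs <- scoring_functions("dock", "Glide", "lower_is_better")
#' tbl <- tibble::tibble(ligand_id = c("a", "b"), dock = c(-9.1, -8.7))
#' relative_ranks(tbl, specs)
#' @export
relative_ranks <- function(table, specs,
                           missing_policy = c("worst_rank", "omit")) {
  missing_policy <- rlang::arg_match(missing_policy)
  fn_cols <- setdiff(names(table), "ligand_id")
  directions <- spec_direction(specs, fn_cols)

  ranks <- purrr::map2_dfr(fn_cols, directions, function(fn, dir) {
    score <- table[[fn]]
    observed <- !is.na(score)
    n_ranked <- sum(observed)
    oriented <- if (dir == "lower_is_better") score else -score
    r <- rep(NA_real_, length(score))
    r[observed] <- rank(oriented[observed], ties.method = "average")
    out <- tibble(ligand_id = table$ligand_id, function_name = fn,
                  rank = r, n_ranked = n_ranked)
    if (missing_policy == "worst_rank") {
      out$rank[!observed] <- n_ranked + 1
      out
    } else {
      out[observed, ]
    }
  })
  attr(ranks, "target_id") <- attr(table, "target_id")
  attr(ranks, "ligand_ids") <- table$ligand_id
  ranks
}

#' Borda count and aggregated consensus rank
#'
#' Adds each ligand's relative ranks across all scoring functions that
#' ranked it (the Borda count) and ranks the sums ascending, with average
#' ranks on ties, to yield the aggregated consensus rank. Low aggregated
#' rank indicates favorable consensus binding.
#'
#' @param ranks Long rank tibble from [relative_ranks()].
#' @return A tibble `ligand_id`, `n_functions`, `borda`, `aggregated_rank`,
#'   ordered by `aggregated_rank`. Ligands with no ranks at all (possible
#'   under the `"omit"` missing policy) are excluded with a warning.
#' @export
borda_aggregate <- function(ranks) {
  if (nrow(ranks) == 0) abort("Rank table is empty.")
  all_ligands <- attr(ranks, "ligand_ids") %||% unique(ranks$ligand_id)
  out <- ranks |>
    dplyr::group_by(.data$ligand_id) |>
    dplyr::summarise(n_functions = dplyr::n(), borda = sum(.data$rank),
                     .groups = "drop")
  dropped <- setdiff(all_ligands, out$ligand_id)
  if (length(dropped) > 0) {
    warn(paste0("Ligand(s) with no ranks excluded from aggregation: ",
                paste(dropped, collapse = ", ")))
  }
  out$aggregated_rank <- rank(out$borda, ties.method = "average")
  dplyr::arrange(out, .data$aggregated_rank)
}

#' Exponential consensus rank (ECR)
#'
#' Models each scoring function's rank as exponentially distributed and sums
#' the decayed ranks: `ecr(i) = sum_j c * exp(-r_ij / sigma)` over functions
#' that ranked ligand i, with `c = 1/sigma` when `prefactor = TRUE` (the
#' normalized form, default) and `c = 1` otherwise. ECR rewards compounds
#' ranked consistently high by at least some functions; larger values
#' indicate more favorable consensus binding. The result is nearly
#' insensitive to `sigma`; 10 is the conventional choice.
#'
#' @param ranks Long rank tibble from [relative_ranks()].
#' @param sigma Positive exponential scale (default 10).
#' @param prefactor Include the `1/sigma` normalization? Default `TRUE`.
#' @return A tibble `ligand_id`, `ecr`, ordered by decreasing `ecr`.
#' @export
ecr_scores <- function(ranks, sigma = 10, prefactor = TRUE) {
  if (!is.numeric(sigma) || length(sigma) != 1 || sigma <= 0) {
    abort("sigma must be a single positive number.")
  }
  cc <- if (prefactor) 1 / sigma else 1
  ranks |>
    dplyr::group_by(.data$ligand_id) |>
    dplyr::summarise(ecr = sum(cc * exp(-.data$rank / sigma)),
                     .groups = "drop") |>
    dplyr::arrange(dplyr::desc(.data$ecr))
}

#' Combined consensus table (Borda, aggregated rank, ECR)
#'
#' Convenience wrapper joining [borda_aggregate()] and [ecr_scores()] on the
#' same rank table.
#'
#' @inheritParams ecr_scores
#' @return A tibble `ligand_id`, `n_functions`, `borda`, `aggregated_rank`,
#'   `ecr`, ordered by `aggregated_rank`.
#' @export
consensus_rank <- function(ranks, sigma = 10, prefactor = TRUE) {
  dplyr::left_join(borda_aggregate(ranks),
                   ecr_scores(ranks, sigma = sigma, prefactor = prefactor),
                   by = "ligand_id")
}

#' Per-function preference vote between two ligands
#'
#' For each scoring function with both scores present, applies the
#' function's direction and counts which ligand it prefers. Equal scores
#' count as ties; a missing score on either side makes that function
#' undecided. Used to compare close analogues such as geometric isomers,
#' where the per-function vote explains the consensus-rank difference.
#'
#' @param table Score table tibble.
#' @param specs Scoring-function metadata.
#' @param ligand_a,ligand_b Ligand identifiers present in `table`.
#' @param detail Return the per-function vote (`TRUE`) instead of the
#'   summary counts.
#' @return With `detail = FALSE` (default), a one-row tibble with columns
#'   `ligand_a`, `ligand_b`, `favors_a`, `favors_b`, `ties`, `undecided`
#'   (counts summing to the number of functions). With `detail = TRUE`, one
#'   row per function with its scores and vote.
#' @examples
#' specs <- scoring_functions(c("f1", "f2"), "Glide",
#'                            c("lower_is_better", "lower_is_better"))
#' tbl <- tibble::tibble(ligand_id = c("a", "b"),
#'                       f1 = c(-9.1, -8.7), f2 = c(-3173.9, -3170.9))
#' majority_vote_preference(tbl, specs, "a", "b")
#' @export
majority_vote_preference <- function(table, specs, ligand_a, ligand_b,
                                     detail = FALSE) {
  missing_lig <- setdiff(c(ligand_a, ligand_b), table$ligand_id)
  if (length(missing_lig) > 0) {
    abort(paste0("Ligand(s) not in score table: ",
                 paste(missing_lig, collapse = ", ")))
  }
  fn_cols <- setdiff(names(table), "ligand_id")
  directions <- spec_direction(specs, fn_cols)
  ia <- match(ligand_a, table$ligand_id)
  ib <- match(ligand_b, table$ligand_id)

  votes <- purrr::map2_dfr(fn_cols, directions, function(fn, dir) {
    sa <- table[[fn]][ia]
    sb <- table[[fn]][ib]
    vote <- if (is.na(sa) || is.na(sb)) {
      "undecided"
    } else if (sa == sb) {
      "tie"
    } else if ((dir == "lower_is_better") == (sa < sb)) {
      "a"
    } else {
      "b"
    }
    tibble(function_name = fn, direction = dir,
           score_a = sa, score_b = sb, vote = vote)
  })
  if (detail) return(votes)
  tibble(
    ligand_a = ligand_a, ligand_b = ligand_b,
    favors_a = sum(votes$vote == "a"),
    favors_b = sum(votes$vote == "b"),
    ties = sum(votes$vote == "tie"),
    undecided = sum(votes$vote == "undecided")
  )
}

#' Write rank and consensus tables to CSV
#'
#' `write_rank_matrix()` pivots the long rank table to a `ligand_id` x
#' function matrix; `write_consensus()` writes the consensus tibble as-is.
#'
#' @param ranks Long rank tibble from [relative_ranks()].
#' @param consensus Consensus tibble from [consensus_rank()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_rank_matrix <- function(ranks, path) {
  wide <- tidyr::pivot_wider(ranks[c("ligand_id", "function_name", "rank")],
                             names_from = "function_name",
                             values_from = "rank")
  readr::write_csv(wide, path, na = "")
  invisible(path)
}

#' @rdname write_rank_matrix
#' @export
write_consensus <- function(consensus, path) {
  readr::write_csv(consensus, path, na = "")
  invisible(path)
}
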