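interaction_key <- function(recs) {
  paste(recs$interaction_type, recs$residue_number, recs$residue_type,
        recs$chain, sep = "@")
}

#' Consensus interactions across two docking programs
#'
#' Per ligand, intersects the interaction keys — (interaction type, residue
#' number, residue type, chain) — reported for the poses of two different
#' docking placement algorithms. Only contacts present in both binding
#' modes survive, which raises confidence in the predicted interaction
#' profile; a ligand whose two programs report disjoint contacts (or that
#' appears in only one input) ends up with an empty consensus set,
#' interpreted downstream as lacking a consistent binding mode at the site.
#'
#' @param records_a,records_b Interaction-record tibbles (as from
#'   [read_plip_records()]) from two distinct programs; duplicate contacts
#'   to the same residue collapse under set semantics.
#' @return A tibble of consensus records (`ligand_id`, `interaction_type`,
#'   `residue_number`, `residue_type`, `chain`) with attributes
#'   `ligand_ids` (every ligand seen in either input, first-appearance
#'   order) and `empty_ligands` (those whose consensus is empty).
#' @export
merge_consensus_interactions <- function(records_a, records_b) {
  prog_a <- unique(records_a$program)
  prog_b <- unique(records_b$program)
  if (length(intersect(prog_a, prog_b)) > 0) {
    abort(paste0("Both inputs contain program label(s) ",
                 paste(intersect(prog_a, prog_b), collapse = ", "),
                 "; consensus requires two distinct placement algorithms."))
  }
  ligands <- unique(c(records_a$ligand_id, records_b$ligand_id))
  keys_a <- split(interaction_key(records_a), records_a$ligand_id)
  keys_b <- split(interaction_key(records_b), records_b$ligand_id)

  only_one <- ligands[!(ligands %in% names(keys_a) & ligands %in% names(keys_b))]
  if (length(only_one) > 0) {
    warn(paste0("Ligand(s) present in only one program's records ",
                "(empty consensus): ", paste(only_one, collapse = ", ")))
  }
  rows <- purrr::map_dfr(ligands, function(lig) {
    shared <- intersect(unique(keys_a[[lig]]), unique(keys_b[[lig]]))
    if (length(shared) == 0) return(NULL)
    parts <- strsplit(shared, "@", fixed = TRUE)
    tibble(
      ligand_id = lig,
      interaction_type = purrr::map_chr(parts, 1),
      residue_number = as.integer(purrr::map_chr(parts, 2)),
      residue_type = purrr::map_chr(parts, 3),
      chain = purrr::map_chr(parts, 4)
    )
  })
  if (nrow(rows) == 0) rows <- dplyr::mutate(empty_interaction_records(),
                                             ligand_id = character())
  attr(rows, "ligand_ids") <- ligands
  attr(rows, "empty_ligands") <- setdiff(ligands, unique(rows$ligand_id))
  rows
}

#' Binary consensus interaction fingerprint matrix
#'
#' Encodes consensus interaction sets as a ligand-by-bit binary matrix. The
#' bit universe is the union of all consensus keys; each bit is named
#' `interaction_type@residue_number@residue_type@chain` and ordered
#' lexicographically by (chain, residue number, residue type, interaction
#' type) so serialization is deterministic. Ligands with empty consensus
#' sets keep an all-zero row.
#'
#' @param consensus Consensus tibble from [merge_consensus_interactions()].
#' @param ligand_ids Ligands to include as rows; defaults to the
#'   `ligand_ids` attribute of `consensus` (so empty-consensus ligands are
#'   retained), falling back to the ligands present in `consensus`.
#' @return A tibble with `ligand_id` followed by one 0/1 integer column per
#'   bit; attribute `empty_ligands` lists all-zero rows.
#' @export
build_fingerprint_matrix <- function(consensus, ligand_ids = NULL) {
  ligand_ids <- ligand_ids %||% attr(consensus, "ligand_ids") %||%
    unique(consensus$ligand_id)
  if (length(ligand_ids) < 1) abort("At least one ligand is required.")
  keys <- unique(consensus[c("interaction_type", "residue_number",
                             "residue_type", "chain")])
  ord <- order(keys$chain, keys$residue_number, keys$residue_type,
               keys$interaction_type, method = "radix")
  keys <- keys[ord, ]
  bit_names <- interaction_key(keys)

  per_ligand <- split(interaction_key(consensus), consensus$ligand_id)
  rows <- purrr::map(ligand_ids, function(lig) {
    as.integer(bit_names %in% per_ligand[[lig]])
  })
  fp <- tibble(ligand_id = ligand_ids)
  mat <- do.call(rbind, rows)
  if (length(bit_names) > 0) {
    for (j in seq_along(bit_names)) fp[[bit_names[j]]] <- mat[, j]
  }
  attr(fp, "empty_ligands") <-
    ligand_ids[rowSums(mat %||% matrix(0, length(ligand_ids), 1)) == 0]
  fp
}

fingerprint_bits <- function(fp) {
  as.matrix(fp[setdiff(names(fp), "ligand_id")])
}

#' Pairwise Tanimoto similarity of interaction fingerprints
#'
#' Computes `T(A, B) = |A n B| / |A u B|` on the bit sets of every ligand
#' pair. When both fingerprints are empty the union is empty and `T = 0` by
#' convention (an empty consensus means no consistent binding mode, so
#' empties must not look maximally similar); the diagonal is likewise 0 for
#' empty-fingerprint ligands and 1 otherwise.
#'
#' @param fp Fingerprint tibble from [build_fingerprint_matrix()].
#' @return A symmetric numeric matrix in `[0, 1]` with ligand dimnames and
#'   an `empty_ligands` attribute.
#' @export
tanimoto_matrix <- function(fp) {
  m <- fingerprint_bits(fp)
  inter <- m %*% t(m)
  sizes <- rowSums(m)
  un <- outer(sizes, sizes, "+") - inter
  tt <- ifelse(un == 0, 0, inter / un)
  dimnames(tt) <- list(fp$ligand_id, fp$ligand_id)
  diag(tt) <- ifelse(sizes > 0, 1, 0)
  attr(tt, "empty_ligands") <- fp$ligand_id[sizes == 0]
  tt
}

#' Hierarchical clustering of interaction fingerprints
#'
#' Agglomerative clustering of ligands on the distance `d = 1 - T` from a
#' Tanimoto similarity matrix, for ordering a clustered fingerprint
#' heatmap. Tie handling and leaf order are deterministic in the input
#' ligand order.
#'
#' @param sim Similarity matrix from [tanimoto_matrix()].
#' @param linkage `"average"` (default), `"complete"` or `"single"`.
#' @return A [stats::hclust] object (merge matrix, heights, labels, leaf
#'   order).
#' @export
cluster_fingerprints <- function(sim, linkage = c("average", "complete", "single")) {
  linkage <- rlang::arg_match(linkage)
  if (nrow(sim) < 2) abort("Clustering requires at least 2 ligands.")
  hclust(as.dist(1 - sim), method = linkage)
}

#' Write fingerprint artifacts
#'
#' `write_fingerprints()` writes the ligand-by-bit 0/1 matrix as CSV;
#' `write_similarity()` the Tanimoto matrix as CSV with a `ligand_id`
#' column; `write_dendrogram_json()` the merge list of a clustering as
#' JSON (`merge`, `height`, `labels`, `order`).
#'
#' @param fp,sim,hc The objects produced by the fingerprint stage.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_fingerprints <- function(fp, path) {
  readr::write_csv(fp, path)
  invisible(path)
}

#' @rdname write_fingerprints
#' @export
write_similarity <- function(sim, path) {
  out <- as_tibble(as.data.frame(unclass(sim)), .name_repair = "minimal")
  out <- dplyr::bind_cols(tibble(ligand_id = rownames(sim)), out)
  readr::write_csv(out, path)
  invisible(path)
}

#' @rdname write_fingerprints
#' @export
write_dendrogram_json <- function(hc, path) {
  obj <- list(
    merge = apply(hc$merge, 1, as.list),
    height = hc$height,
    labels = hc$labels,
    order = hc$order,
    method = hc$method
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
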