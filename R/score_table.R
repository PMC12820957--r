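#' Read a per-target docking score table
#'
#' A score table is a CSV with header `ligand_id` followed by one column per
#' scoring function. Cells are real scores; an empty cell or the token `NA`
#' records a missing score (e.g. a docking failure for that ligand). Every
#' score column must be declared in `specs`; ligands must be unique.
#'
#' @param path CSV file path.
#' @param specs Scoring-function metadata from [scoring_functions()] or
#'   [read_function_specs()].
#' @param target_id Optional label for the protein target (e.g. `"CI"`),
#'   stored as the `target_id` attribute.
#' @return A tibble (`ligand_id` + one numeric column per function) with
#'   attribute `target_id`. Row and column order follow the file.
#' @export
read_score_table <- function(path, specs, target_id = NULL) {
  raw <- readr::read_csv(path, col_types = readr::cols(.default = "c"),
                         na = character(), progress = FALSE)
  if (names(raw)[1] != "ligand_id") {
    abort("Score table must start with a 'ligand_id' column.")
  }
  fn_cols <- names(raw)[-1]
  unknown <- setdiff(fn_cols, specs$name)
  if (length(unknown) > 0) {
    abort(paste0("Score column(s) not declared in the function specs: ",
                 paste(unknown, collapse = ", ")))
  }
  if (anyDuplicated(raw$ligand_id)) {
    dup <- unique(raw$ligand_id[duplicated(raw$ligand_id)])
    abort(paste0("Duplicate ligand_id(s): ", paste(dup, collapse = ", ")))
  }
  parsed <- raw
  for (fn in fn_cols) {
    cell <- trimws(raw[[fn]])
    is_missing <- cell == "" | cell == "NA"
    val <- suppressWarnings(as.numeric(cell))
    bad <- !is_missing & is.na(val)
    if (any(bad)) {
      row <- which(bad)[1]
      abort(paste0("Non-numeric score '", cell[row], "' at row ", row,
                   " (ligand ", raw$ligand_id[row], "), column '", fn, "'."))
    }
    val[is_missing] <- NA_real_
    parsed[[fn]] <- val
  }
  new_score_table(parsed, target_id)
}

new_score_table <- function(tbl, target_id = NULL) {
  tbl <- as_tibble(tbl)
  attr(tbl, "target_id") <- target_id
  tbl
}

#' Write a score table to CSV
#'
#' Missing scores are written as empty cells. Round trips through
#' [read_score_table()] preserve values exactly for decimal representations
#' of up to 15 significant digits.
#'
#' @param table Score table tibble (`ligand_id` + numeric columns).
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_score_table <- function(table, path) {
  out <- table
  for (fn in setdiff(names(out), "ligand_id")) {
    out[[fn]] <- ifelse(is.na(out[[fn]]),
                        "",
                        format(out[[fn]], digits = 15, trim = TRUE,
                               scientific = FALSE))
  }
  readr::write_csv(out, path, na = "")
  invisible(path)
}

#' Read ligand mechanism-class annotations
#'
#' @param path CSV with columns `ligand_id,mech_class`; classes must be one
#'   of `CI_inhibitor`, `CIII_inhibitor`, `uncoupler`.
#' @return A tibble with those two columns.
#' @export
read_annotations <- function(path) {
  ann <- readr::read_csv(path, col_types = readr::cols(.default = "c"),
                         progress = FALSE)
  required <- c("ligand_id", "mech_class")
  if (!all(required %in% names(ann))) {
    abort("Annotation file needs columns ligand_id, mech_class.")
  }
  bad <- !ann$mech_class %in% MECH_CLASSES
  if (any(bad)) {
    abort(paste0("Unknown mech_class value(s): ",
                 paste(unique(ann$mech_class[bad]), collapse = ", ")))
  }
  if (anyDuplicated(ann$ligand_id)) abort("Duplicate ligand_id in annotations.")
  as_tibble(ann[required])
}

#' Read an experimental activity table
#'
#' @param path CSV with columns `ligand_id,pIC50` and an optional `sd`
#'   column of per-ligand standard deviations.
#' @return A tibble `ligand_id`, `pIC50` and (if present) `sd`.
#' @export
read_activity_table <- function(path) {
  raw <- readr::read_csv(path, col_types = readr::cols(.default = "c"),
                         progress = FALSE)
  if (!all(c("ligand_id", "pIC50") %in% names(raw))) {
    abort("Activity file needs columns ligand_id, pIC50.")
  }
  if (anyDuplicated(raw$ligand_id)) {
    dup <- unique(raw$ligand_id[duplicated(raw$ligand_id)])
    abort(paste0("Duplicate ligand_id(s) in activity table: ",
                 paste(dup, collapse = ", ")))
  }
  p <- suppressWarnings(as.numeric(raw$pIC50))
  bad <- is.na(p) | !is.finite(p)
  if (any(bad)) {
    abort(paste0("Non-numeric or non-finite pIC50 for ligand(s): ",
                 paste(raw$ligand_id[bad], collapse = ", ")))
  }
  out <- tibble(ligand_id = raw$ligand_id, pIC50 = p)
  if ("sd" %in% names(raw)) {
    s <- suppressWarnings(as.numeric(raw$sd))
    if (any(!is.na(s) & s < 0)) abort("pIC50 standard deviations must be >= 0.")
    out$sd <- s
  }
  out
}
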