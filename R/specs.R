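#' Declare scoring-function metadata
#'
#' Every scoring function in a cross-docking study carries two pieces of
#' metadata the downstream analysis cannot infer from the numbers alone: the
#' program that produced it and its ranking direction. Docking scores,
#' IFDScores and binding-energy estimates improve downwards
#' (`lower_is_better`), whereas GOLD fitness functions improve upwards
#' (`higher_is_better`).
#'
#' @param name Character vector of unique function identifiers.
#' @param program Character vector (recycled) naming the program of origin,
#'   e.g. `"Glide"`, `"GOLD"`.
#' @param direction Character vector (recycled), each element one of
#'   `"lower_is_better"` or `"higher_is_better"`. No default: the direction
#'   must be stated explicitly for every function.
#'
#' @return A tibble with columns `name`, `program`, `direction`.
#' @examples
#' scoring_functions(
#'   name = c("glide_docking_score", "gold_chemplp_fitness"),
#'   program = c("Glide", "GOLD"),
#'   direction = c("lower_is_better", "higher_is_better")
#' )
#' @export
scoring_functions <- function(name, program, direction) {
  specs <- tibble(
    name = as.character(name),
    program = as.character(program),
    direction = as.character(direction)
  )
  validate_function_specs(specs)
}

#' Read scoring-function metadata from CSV or YAML
#'
#' The file must provide, per function, the fields `name`, `program` and
#' `direction`. CSV files need a header with those columns; YAML files hold
#' either a list of mappings or a mapping of name -> {program, direction}.
#'
#' @param path Path to a `.csv`, `.yml` or `.yaml` file.
#' @return A validated tibble as from [scoring_functions()].
#' @export
read_function_specs <- function(path) {
  if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    raw <- yaml::read_yaml(path)
    if (!is.null(names(raw)) && all(nzchar(names(raw)))) {
      specs <- purrr::imap_dfr(raw, function(x, nm) {
        tibble(name = nm, program = x$program %||% NA_character_,
               direction = x$direction %||% NA_character_)
      })
    } else {
      specs <- purrr::map_dfr(raw, function(x) {
        tibble(name = x$name %||% NA_character_,
               program = x$program %||% NA_character_,
               direction = x$direction %||% NA_character_)
      })
    }
  } else {
    specs <- readr::read_csv(path, col_types = readr::cols(.default = "c"),
                             progress = FALSE)
  }
  required <- c("name", "program", "direction")
  missing_cols <- setdiff(required, names(specs))
  if (length(missing_cols) > 0) {
    abort(paste0("Function spec file lacks column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  validate_function_specs(as_tibble(specs[required]))
}

validate_function_specs <- function(specs) {
  if (nrow(specs) == 0) abort("At least one scoring function is required.")
  if (anyNA(specs$name) || any(!nzchar(specs$name))) {
    abort("Scoring-function names must be nonempty.")
  }
  if (anyDuplicated(specs$name)) {
    dup <- unique(specs$name[duplicated(specs$name)])
    abort(paste0("Duplicate scoring-function name(s): ",
                 paste(dup, collapse = ", ")))
  }
  bad <- !specs$direction %in% c("lower_is_better", "higher_is_better")
  if (any(bad)) {
    abort(paste0(
      "Invalid or missing direction for function(s): ",
      paste(specs$name[bad], collapse = ", "),
      " (use 'lower_is_better' or 'higher_is_better')."
    ))
  }
  specs
}

spec_direction <- function(specs, fn) {
  i <- match(fn, specs$name)
  if (anyNA(i)) {
    abort(paste0("No direction metadata for function(s): ",
                 paste(fn[is.na(i)], collapse = ", ")))
  }
  specs$direction[i]
}
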