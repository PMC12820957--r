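# Map PLIP XML element names to the interaction-type vocabulary.
PLIP_ELEMENT_MAP <- c(
  hydrophobic_interaction = "hydrophobic_interaction",
  hydrogen_bond = "hydrogen_bond",
  pi_stack = "pi_stack",
  pi_cation_interaction = "pi_cation",
  pi_cation = "pi_cation",
  salt_bridge = "salt_bridge",
  water_bridge = "water_bridge",
  halogen_bond = "halogen_bond",
  metal_complex = "metal_complex"
)

#' Read protein-ligand interaction records from a PLIP report
#'
#' Parses either a PLIP XML report (the `<interaction>`-style children under
#' each `<interactions>` node of a binding site) or an equivalent flat CSV
#' with columns `interaction_type,residue_number,residue_type,chain`. One
#' record is returned per reported contact: the typed residue identity
#' (interaction type, residue number, 3-letter residue code, chain) plus the
#' ligand and program labels supplied by the caller. Residue codes are
#' uppercased; chains are kept case-sensitive as authored in the PDB file.
#' Water bridges and salt bridges are retained as distinct types, never
#' collapsed into hydrogen bonds. Unknown XML attributes or extra child
#' elements inside a contact are tolerated; an unknown interaction *class*
#' element is an error.
#'
#' @param path Path to a PLIP XML report or a flat CSV.
#' @param ligand_id Ligand identifier to stamp on every record.
#' @param program Origin label (docking program) to stamp on every record.
#' @return A tibble with columns `interaction_type`, `residue_number`,
#'   `residue_type`, `chain`, `ligand_id`, `program`; zero rows when the
#'   report lists no contacts.
#' @export
read_plip_records <- function(path, ligand_id, program) {
  first <- readLines(path, n = 1L, warn = FALSE)
  if (length(first) > 0 && grepl("^\\s*<", first[1])) {
    recs <- parse_plip_xml(path)
  } else {
    recs <- parse_plip_csv(path)
  }
  recs$ligand_id <- rep(as.character(ligand_id), nrow(recs))
  recs$program <- rep(as.character(program), nrow(recs))
  validate_interaction_records(recs)
}

parse_plip_xml <- function(path) {
  doc <- tryCatch(xml2::read_xml(path),
                  error = function(e) abort(paste0("Unparseable PLIP XML: ",
                                                   conditionMessage(e))))
  nodes <- xml2::xml_find_all(doc, ".//interactions/*/*")
  if (length(nodes) == 0) return(empty_interaction_records())
  elem <- xml2::xml_name(nodes)
  unknown <- setdiff(unique(elem), names(PLIP_ELEMENT_MAP))
  if (length(unknown) > 0) {
    abort(paste0("Unknown PLIP interaction element(s): ",
                 paste(unknown, collapse = ", ")))
  }
  field <- function(node, name) xml2::xml_text(xml2::xml_find_first(node, name))
  tibble(
    interaction_type = unname(PLIP_ELEMENT_MAP[elem]),
    residue_number = as.integer(purrr::map_chr(nodes, field, "resnr")),
    residue_type = toupper(purrr::map_chr(nodes, field, "restype")),
    chain = purrr::map_chr(nodes, field, "reschain")
  )
}

parse_plip_csv <- function(path) {
  raw <- readr::read_csv(path, col_types = readr::cols(.default = "c"),
                         progress = FALSE)
  required <- c("interaction_type", "residue_number", "residue_type", "chain")
  missing_cols <- setdiff(required, names(raw))
  if (length(missing_cols) > 0) {
    abort(paste0("Interaction CSV lacks column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  if (nrow(raw) == 0) return(empty_interaction_records())
  unknown <- setdiff(unique(raw$interaction_type), names(PLIP_ELEMENT_MAP))
  if (length(unknown) > 0) {
    abort(paste0("Unknown interaction type(s): ",
                 paste(unknown, collapse = ", ")))
  }
  tibble(
    interaction_type = unname(PLIP_ELEMENT_MAP[raw$interaction_type]),
    residue_number = as.integer(raw$residue_number),
    residue_type = toupper(raw$residue_type),
    chain = raw$chain
  )
}

empty_interaction_records <- function() {
  tibble(interaction_type = character(), residue_number = integer(),
         residue_type = character(), chain = character())
}

validate_interaction_records <- function(recs) {
  if (nrow(recs) == 0) return(as_tibble(recs))
  if (anyNA(recs$residue_number) || any(recs$residue_number < 1)) {
    abort("Residue numbers must be integers >= 1.")
  }
  if (any(nchar(recs$residue_type) != 3)) {
    bad <- unique(recs$residue_type[nchar(recs$residue_type) != 3])
    abort(paste0("Residue types must be 3-letter codes; got: ",
                 paste(bad, collapse = ", ")))
  }
  as_tibble(recs)
}
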