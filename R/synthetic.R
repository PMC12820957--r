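#' Default synthetic scoring-function panel
#'
#' Eleven scoring functions from two simulated docking programs, mirroring
#' a typical cross-docking panel: five Glide-side estimators (docking
#' score, IFD composite score, MM-GBSA binding energy, two minimization
#' energies), all lower-is-better, and six GOLD-side ones — three genetic
#' algorithm fitness functions (higher-is-better) plus three rescoring
#' energies (lower-is-better). Each function carries its generative
#' parameters: gain on the latent affinity, constant offset, per-function
#' noise sd, and a per-target additive offset emulating target-dependent
#' scoring behavior.
#'
#' @return A tibble with columns `name`, `program`, `direction`, `gain`,
#'   `offset`, `noise_sd`, `target_offset_CI`, `target_offset_CIII`.
#' @export
default_function_specs <- function() {
  tibble(
    name = c("glide_docking_score", "glide_ifdscore", "mmgbsa_dg_bind_glide",
             "mbae_aset_glide", "mbae_del_glide",
             "gold_chemplp_fitness", "gold_chemscore_fitness",
             "gold_goldscore_fitness", "mmgbsa_dg_bind_gold",
             "mbae_aset_gold", "mbae_del_gold"),
    program = c(rep("progA", 5), rep("progB", 6)),
    direction = c(rep("lower_is_better", 5), rep("higher_is_better", 3),
                  rep("lower_is_better", 3)),
    gain = c(1.0, 1.2, 0.9, 0.7, 0.6, 1.1, 0.8, 1.0, 0.9, 0.7, 0.6),
    offset = c(8, 3170, 45, 240, 180, 70, 25, 50, 45, 240, 180),
    noise_sd = c(0.8, 0.7, 1.0, 1.2, 1.2, 0.8, 0.9, 0.8, 1.0, 1.2, 1.2),
    target_offset_CI = c(0, 0.3, -0.2, 0.1, 0, 0.2, 0, -0.1, 0.1, 0, 0.2),
    target_offset_CIII = c(0.2, -0.1, 0.3, 0, -0.2, 0, 0.1, 0.2, -0.3, 0.1, 0)
  )
}

#' Configuration of a synthetic cross-docking study
#'
#' Defines the generative model behind [generate_study()]: a single latent
#' affinity per (ligand, target) drives docking scores, interaction
#' profiles and experimental activity, so every downstream stage has known
#' ground truth. Defaults emulate the study conditions of a two-target
#' mitochondrial inhibitor panel: 14 complex-I inhibitors, 11 complex-III
#' inhibitors and 3 uncouplers (28 ligands) scored by 11 functions from two
#' programs, a 21-key consensus interaction core per target, and pIC50
#' activities for the binders of the activity target.
#'
#' @param n_ci,n_ciii,n_unc Class sizes (defaults 14, 11, 3).
#' @param functions Function panel tibble as from [default_function_specs()].
#' @param binder_mean,binder_sd Latent affinity distribution of a target's
#'   true binders (default Normal(2.5, 1): a moderate separation for which
#'   single-function classification is good but imperfect).
#' @param nonbinder_mean,nonbinder_sd Latent affinity of nonbinders
#'   (default Normal(0, 1)).
#' @param program_sd Sd of the noise shared by all functions of one program
#'   for a given ligand (default 0.5); induces the within-program block
#'   correlation seen in real rank heatmaps.
#' @param p_fail Probability that a (ligand, program, target) docking run
#'   fails entirely, leaving that program's scores missing (default 0.05).
#' @param core_size Number of interaction keys in each target's binder core
#'   (default 21); cores are disjoint across targets.
#' @param p_core Per-program probability that a binder's pose reports a
#'   given core key (default 0.8), so a consensus fingerprint covers each
#'   core key with probability about `p_core^2`.
#' @param nonbinder_core_prob Per-program probability that a nonbinder
#'   reports a core key (default 0.05).
#' @param lambda_spur Mean number of spurious (non-core) keys per (ligand,
#'   program) (default 2).
#' @param gamma0,gamma1,activity_sd Activity model
#'   `pIC50 = gamma0 + gamma1 * affinity + Normal(0, activity_sd)` for
#'   binders of `activity_target` (defaults 6, 0.8, 0.3).
#' @param activity_target Target whose binders get measured activities
#'   (default `"CIII"`, emulating an SCR-type assay).
#' @return A validated list of class `study_config`.
#' @export
study_config <- function(n_ci = 14, n_ciii = 11, n_unc = 3,
                         functions = default_function_specs(),
                         binder_mean = 2.5, binder_sd = 1,
                         nonbinder_mean = 0, nonbinder_sd = 1,
                         program_sd = 0.5, p_fail = 0.05,
                         core_size = 21, p_core = 0.8,
                         nonbinder_core_prob = 0.05, lambda_spur = 2,
                         gamma0 = 6, gamma1 = 0.8, activity_sd = 0.3,
                         activity_target = "CIII") {
  cfg <- list(
    n_ci = n_ci, n_ciii = n_ciii, n_unc = n_unc, functions = functions,
    binder_mean = binder_mean, binder_sd = binder_sd,
    nonbinder_mean = nonbinder_mean, nonbinder_sd = nonbinder_sd,
    program_sd = program_sd, p_fail = p_fail, core_size = core_size,
    p_core = p_core, nonbinder_core_prob = nonbinder_core_prob,
    lambda_spur = lambda_spur, gamma0 = gamma0, gamma1 = gamma1,
    activity_sd = activity_sd, activity_target = activity_target,
    targets = c("CI", "CIII")
  )
  validate_study_config(cfg)
  structure(cfg, class = "study_config")
}

validate_study_config <- function(cfg) {
  bad <- character()
  for (f in c("n_ci", "n_ciii", "n_unc", "core_size")) {
    if (!is.numeric(cfg[[f]]) || cfg[[f]] < 0 || cfg[[f]] != round(cfg[[f]])) {
      bad <- c(bad, f)
    }
  }
  for (f in c("binder_sd", "nonbinder_sd", "program_sd", "activity_sd",
              "lambda_spur")) {
    if (!is.numeric(cfg[[f]]) || cfg[[f]] < 0) bad <- c(bad, f)
  }
  for (f in c("p_fail", "p_core", "nonbinder_core_prob")) {
    if (!is.numeric(cfg[[f]]) || cfg[[f]] < 0 || cfg[[f]] > 1) bad <- c(bad, f)
  }
  if (!cfg$gamma1 > 0) bad <- c(bad, "gamma1")
  if (!cfg$activity_target %in% cfg$targets) bad <- c(bad, "activity_target")
  fns <- cfg$functions
  if (!all(c("name", "program", "direction", "gain", "offset", "noise_sd",
             "target_offset_CI", "target_offset_CIII") %in% names(fns))) {
    bad <- c(bad, "functions")
  } else {
    validate_function_specs(fns[c("name", "program", "direction")])
    if (any(fns$gain <= 0)) bad <- c(bad, "functions$gain")
    if (any(fns$noise_sd < 0)) bad <- c(bad, "functions$noise_sd")
  }
  if (length(bad) > 0) {
    abort(paste0("Invalid study_config field(s): ",
                 paste(unique(bad), collapse = ", ")))
  }
  invisible(cfg)
}

study_ligands <- function(cfg) {
  tibble(
    ligand_id = c(sprintf("ci_%02d", seq_len(cfg$n_ci)),
                  sprintf("ciii_%02d", seq_len(cfg$n_ciii)),
                  sprintf("unc_%02d", seq_len(cfg$n_unc))),
    mech_class = c(rep("CI_inhibitor", cfg$n_ci),
                   rep("CIII_inhibitor", cfg$n_ciii),
                   rep("uncoupler", cfg$n_unc))
  )
}

is_binder <- function(mech_class, target) {
  (target == "CI" & mech_class == "CI_inhibitor") |
    (target == "CIII" & mech_class == "CIII_inhibitor")
}

gen_latents <- function(cfg, ann) {
  purrr::map_dfr(cfg$targets, function(tg) {
    binder <- is_binder(ann$mech_class, tg)
    mu <- ifelse(binder, cfg$binder_mean, cfg$nonbinder_mean)
    s <- ifelse(binder, cfg$binder_sd, cfg$nonbinder_sd)
    tibble(ligand_id = ann$ligand_id, target = tg, binder = binder,
           affinity = rnorm(nrow(ann), mu, s))
  })
}

gen_scores_one_target <- function(cfg, latents_t) {
  fns <- cfg$functions
  n <- nrow(latents_t)
  programs <- unique(fns$program)
  u <- matrix(rnorm(n * length(programs), 0, cfg$program_sd), nrow = n,
              dimnames = list(NULL, programs))
  failed <- matrix(runif(n * length(programs)) < cfg$p_fail, nrow = n,
                   dimnames = list(NULL, programs))
  tg <- latents_t$target[1]
  tbl <- tibble(ligand_id = latents_t$ligand_id)
  for (j in seq_len(nrow(fns))) {
    f <- fns[j, ]
    t_off <- if (tg == "CI") f$target_offset_CI else f$target_offset_CIII
    raw <- f$gain * latents_t$affinity + f$offset + t_off +
      u[, f$program] + rnorm(n, 0, f$noise_sd)
    score <- if (f$direction == "higher_is_better") raw else -raw
    score[failed[, f$program]] <- NA_real_
    tbl[[f$name]] <- score
  }
  new_score_table(tbl, target_id = tg)
}

#' Generate synthetic score tables with known latent affinities
#'
#' Draws one latent affinity per (ligand, target) from the class-dependent
#' distributions in `cfg`, then emits, per scoring function,
#' `raw = gain * affinity + offset + target_offset + u + eps` with `u` a
#' program-shared ligand noise and `eps` function noise; the recorded score
#' is `raw` for higher-is-better functions and `-raw` otherwise. Each
#' (ligand, program) pair fails jointly with probability `p_fail`, leaving
#' all of that program's scores missing for the ligand.
#'
#' @param cfg A [study_config()].
#' @param seed Optional integer seed; when given, the draw is reproducible
#'   and the session RNG state is left untouched.
#' @return A list with `scores` (named list of per-target score tables),
#'   `latents` (tibble `ligand_id`, `target`, `binder`, `affinity`) and
#'   `annotations`.
#' @export
generate_scores <- function(cfg, seed = NULL) {
  validate_study_config(cfg)
  run <- function() {
    ann <- study_ligands(cfg)
    latents <- gen_latents(cfg, ann)
    scores <- lapply(setNames(cfg$targets, cfg$targets), function(tg) {
      gen_scores_one_target(cfg, latents[latents$target == tg, ])
    })
    list(scores = scores, latents = latents, annotations = ann)
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

# Deterministic disjoint core interaction keys per target.
core_keys <- function(target, size) {
  aa <- c("PHE", "LEU", "MET", "THR", "HIS", "TYR", "GLY", "SER", "PRO", "ALA", "VAL")
  types <- c("hydrophobic_interaction", "hydrogen_bond",
             "hydrophobic_interaction", "pi_stack", "hydrogen_bond")
  base <- if (target == "CI") 80L else 300L
  chains <- if (target == "CI") c("C", "Q") else c("E", "F")
  tibble(
    interaction_type = types[(seq_len(size) - 1) %% length(types) + 1],
    residue_number = base + 3L * seq_len(size),
    residue_type = aa[(seq_len(size) - 1) %% length(aa) + 1],
    chain = chains[(seq_len(size) - 1) %% length(chains) + 1]
  )
}

spurious_pool <- function() {
  aa <- c("ARG", "LYS", "ASP", "GLU", "ASN", "GLN", "TRP", "ILE")
  tibble(
    interaction_type = rep(c("hydrophobic_interaction", "hydrogen_bond",
                             "water_bridge", "salt_bridge"), each = 50),
    residue_number = 500L + seq_len(200),
    residue_type = aa[(seq_len(200) - 1) %% length(aa) + 1],
    chain = "X"
  )
}

#' Generate per-program PLIP-style interaction records
#'
#' Each target owns a disjoint core of `core_size` interaction keys. A true
#' binder's pose reports each core key with probability `p_core`,
#' independently per program, so the two-program consensus retains a core
#' key with probability about `p_core^2`; nonbinders report core keys with
#' probability `nonbinder_core_prob`. Every (ligand, program) additionally
#' gains `Poisson(lambda_spur)` spurious keys drawn from a pool outside all
#' cores, which rarely survive the consensus intersection.
#'
#' @inheritParams generate_scores
#' @param latents Latents tibble from [generate_scores()].
#' @return A named list per target; each element is a named list per
#'   program (`progA`, `progB`) of interaction-record tibbles.
#' @export
generate_interactions <- function(cfg, latents, seed = NULL) {
  validate_study_config(cfg)
  programs <- unique(cfg$functions$program)
  pool <- spurious_pool()
  run <- function() {
    lapply(setNames(cfg$targets, cfg$targets), function(tg) {
      core <- core_keys(tg, cfg$core_size)
      lat <- latents[latents$target == tg, ]
      lapply(setNames(programs, programs), function(pr) {
        purrr::map_dfr(seq_len(nrow(lat)), function(i) {
          p <- if (lat$binder[i]) cfg$p_core else cfg$nonbinder_core_prob
          keep <- runif(nrow(core)) < p
          n_spur <- rpois(1, cfg$lambda_spur)
          spur <- pool[sample.int(nrow(pool), min(n_spur, nrow(pool))), ]
          recs <- dplyr::bind_rows(core[keep, ], spur)
          if (nrow(recs) == 0) return(NULL)
          dplyr::mutate(recs, ligand_id = lat$ligand_id[i], program = pr)
        })
      })
    })
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

gen_activities <- function(cfg, latents) {
  lat <- latents[latents$target == cfg$activity_target & latents$binder, ]
  tibble(
    ligand_id = lat$ligand_id,
    pIC50 = cfg$gamma0 + cfg$gamma1 * lat$affinity +
      rnorm(nrow(lat), 0, cfg$activity_sd),
    sd = rep(cfg$activity_sd, nrow(lat))
  )
}

#' Generate a complete synthetic cross-docking study
#'
#' Composes [generate_scores()], [generate_interactions()] and an activity
#' draw (`pIC50 = gamma0 + gamma1 * affinity + noise` for binders of the
#' activity target) into a single reproducible bundle with ground truth.
#'
#' @inheritParams generate_scores
#' @return A `study_bundle`: list with `scores` (per-target score tables),
#'   `specs` (name/program/direction tibble), `annotations`, `interactions`
#'   (per target, per program), `activities`, `latents`, `config`, `seed`.
#' @examples
#' bundle <- generate_study(study_config(), seed = 1)
#' names(bundle$scores)
#' @export
generate_study <- function(cfg = study_config(), seed = NULL) {
  validate_study_config(cfg)
  run <- function() {
    sc <- generate_scores(cfg)
    ints <- generate_interactions(cfg, sc$latents)
    acts <- gen_activities(cfg, sc$latents)
    structure(
      list(scores = sc$scores,
           specs = cfg$functions[c("name", "program", "direction")],
           annotations = sc$annotations, interactions = ints,
           activities = acts, latents = sc$latents, config = cfg,
           seed = seed),
      class = "study_bundle"
    )
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

#' @exportS3Method base::print
print.study_bundle <- function(x, ...) {
  cat("<study_bundle>",
      "\n  targets:", paste(names(x$scores), collapse = ", "),
      "\n  ligands:", nrow(x$annotations),
      paste0("(", paste(table(x$annotations$mech_class), collapse = "/"), ")"),
      "\n  scoring functions:", nrow(x$specs),
      "\n  activities:", nrow(x$activities), "ligands\n")
  invisible(x)
}

#' Write a study bundle to disk in the package's interchange formats
#'
#' Emits per-target score CSVs, the function-spec CSV, annotations,
#' per-(target, program) interaction CSVs, the activity CSV and the latent
#' ground truth, so a generated study can be re-read and analysed through
#' the same readers used for real docking output.
#'
#' @param bundle A `study_bundle`.
#' @param dir Output directory (created if absent).
#' @return Named character vector of the written paths, invisibly.
#' @export
write_study_bundle <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c()
  for (tg in names(bundle$scores)) {
    p <- file.path(dir, paste0("scores_", tg, ".csv"))
    write_score_table(bundle$scores[[tg]], p)
    paths[paste0("scores_", tg)] <- p
    for (pr in names(bundle$interactions[[tg]])) {
      q <- file.path(dir, paste0("interactions_", tg, "_", pr, ".csv"))
      readr::write_csv(bundle$interactions[[tg]][[pr]], q)
      paths[paste0("interactions_", tg, "_", pr)] <- q
    }
  }
  readr::write_csv(bundle$specs, file.path(dir, "function_specs.csv"))
  readr::write_csv(bundle$annotations, file.path(dir, "annotations.csv"))
  readr::write_csv(bundle$activities, file.path(dir, "activities.csv"))
  readr::write_csv(bundle$latents, file.path(dir, "latents.csv"))
  paths <- c(paths, specs = file.path(dir, "function_specs.csv"),
             annotations = file.path(dir, "annotations.csv"),
             activities = file.path(dir, "activities.csv"),
             latents = file.path(dir, "latents.csv"))
  invisible(paths)
}
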