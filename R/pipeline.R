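#' Configure a full analysis run
#'
#' Bundles every tunable of the end-to-end analysis: the input study
#' (either a synthetic [study_config()] or paths to on-disk tables), the
#' consensus options (ECR scale `sigma`, prefactor, missing-score policy),
#' the fingerprint clustering linkage, the positive class per target for
#' threshold classification, an output directory and the seed.
#'
#' @param out_dir Output directory for artifacts.
#' @param seed Integer seed driving synthetic generation.
#' @param synthetic A [study_config()] used when `inputs` is `NULL`.
#' @param inputs Optional named list of file paths: `scores` (named by
#'   target), `specs`, `annotations`, `interactions` (per target, a named
#'   list per program of flat CSVs), and optionally `activities`.
#' @param sigma,prefactor ECR parameters (defaults 10, `TRUE`).
#' @param missing_policy `"worst_rank"` or `"omit"`.
#' @param linkage Fingerprint clustering linkage (default `"average"`).
#' @param positive_class Named character vector mapping target to its
#'   positive mechanism class; default `<target>_inhibitor`.
#' @param activity_target Target whose scores are correlated with pIC50.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(out_dir, seed = 1, synthetic = study_config(),
                            inputs = NULL, sigma = 10, prefactor = TRUE,
                            missing_policy = c("worst_rank", "omit"),
                            linkage = c("average", "complete", "single"),
                            positive_class = NULL, activity_target = "CIII") {
  structure(
    list(out_dir = out_dir, seed = seed, synthetic = synthetic,
         inputs = inputs, sigma = sigma, prefactor = prefactor,
         missing_policy = rlang::arg_match(missing_policy),
         linkage = rlang::arg_match(linkage),
         positive_class = positive_class, activity_target = activity_target),
    class = "pipeline_config"
  )
}

load_study_inputs <- function(inputs) {
  specs <- read_function_specs(inputs$specs)
  scores <- purrr::imap(inputs$scores, function(p, tg) {
    read_score_table(p, specs, target_id = tg)
  })
  interactions <- purrr::map(inputs$interactions, function(by_prog) {
    purrr::imap(by_prog, function(p, pr) {
      recs <- readr::read_csv(p, col_types = readr::cols(.default = "c"),
                              progress = FALSE)
      recs$residue_number <- as.integer(recs$residue_number)
      validate_interaction_records(as_tibble(recs))
    })
  })
  list(
    scores = scores, specs = specs,
    annotations = if (!is.null(inputs$annotations)) read_annotations(inputs$annotations),
    interactions = interactions,
    activities = if (!is.null(inputs$activities)) read_activity_table(inputs$activities)
  )
}

#' Run the full post-docking consensus analysis
#'
#' Executes, per target: direction-aware relative ranking, Borda/aggregated
#' and ECR consensus, per-function KDE-intersection thresholds with
#' confusion-matrix metrics against the target's positive class, consensus
#' interaction fingerprints with Tanimoto similarity and hierarchical
#' clustering — then correlates scores and consensus values with
#' experimental pIC50 where activities exist. All artifacts (`ranks.csv`,
#' `consensus.csv`, `thresholds.json`, `metrics.json`, `fingerprints.csv`,
#' `similarity.csv`, `dendrogram.json` per target, plus
#' `correlations.json` and `manifest.json`) are written under
#' `cfg$out_dir`; reruns with the same config and seed are byte-identical.
#' Input files are never modified.
#'
#' @param cfg A [pipeline_config()].
#' @return The run manifest (config hash, seed, artifact paths, stage
#'   notes), invisibly as a list; it is also written as `manifest.json`.
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "pipeline_config"))
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  study <- if (is.null(cfg$inputs)) {
    generate_study(cfg$synthetic, seed = cfg$seed)
  } else {
    load_study_inputs(cfg$inputs)
  }
  manifest <- list(
    config_hash = rlang::hash(unclass(cfg)),
    seed = cfg$seed,
    package_version = as.character(utils::packageVersion("dockconsensus")),
    artifacts = list(), notes = list()
  )

  for (tg in names(study$scores)) {
    tdir <- file.path(cfg$out_dir, tg)
    dir.create(tdir, showWarnings = FALSE)
    tbl <- study$scores[[tg]]
    ranks <- relative_ranks(tbl, study$specs, missing_policy = cfg$missing_policy)
    cons <- consensus_rank(ranks, sigma = cfg$sigma, prefactor = cfg$prefactor)
    write_rank_matrix(ranks, file.path(tdir, "ranks.csv"))
    write_consensus(cons, file.path(tdir, "consensus.csv"))
    manifest$artifacts[[tg]] <- c(ranks = file.path(tdir, "ranks.csv"),
                                  consensus = file.path(tdir, "consensus.csv"))

    if (!is.null(study$annotations)) {
      pos_class <- (cfg$positive_class %||%
        setNames(paste0(names(study$scores), "_inhibitor"),
                 names(study$scores)))[[tg]]
      truth <- setNames(
        ifelse(study$annotations$mech_class == pos_class, "positive", "negative"),
        study$annotations$ligand_id
      )
      thr_list <- list()
      met_list <- list()
      for (fn in setdiff(names(tbl), "ligand_id")) {
        scores_fn <- setNames(tbl[[fn]], tbl$ligand_id)
        res <- tryCatch({
          model <- intersection_threshold(
            scores_fn[truth[names(scores_fn)] == "positive"],
            scores_fn[truth[names(scores_fn)] == "negative"],
            function_name = fn
          )
          pred <- suppressWarnings(classify_by_threshold(scores_fn, model))
          met <- classification_metrics(
            data.frame(truth = unname(truth[pred$ligand_id]),
                       predicted = pred$label)
          )
          list(model = model, metrics = met)
        }, error = function(e) {
          manifest$notes[[paste(tg, fn, sep = "/")]] <<- conditionMessage(e)
          NULL
        })
        if (!is.null(res)) {
          thr_list[[fn]] <- list(
            function_name = fn, threshold = res$model$threshold,
            positive_side = res$model$positive_side, domain = res$model$domain,
            bandwidth = as.list(res$model$bandwidth),
            crossings = res$model$crossings
          )
          m <- as.list(res$metrics)
          m$mcc_rounded <- round(m$mcc, 3)
          m$bac_rounded <- round(m$bac, 3)
          met_list[[fn]] <- m
        }
      }
      jsonlite::write_json(thr_list, file.path(tdir, "thresholds.json"),
                           auto_unbox = TRUE, digits = NA, pretty = TRUE)
      jsonlite::write_json(met_list, file.path(tdir, "metrics.json"),
                           auto_unbox = TRUE, digits = NA, pretty = TRUE,
                           na = "null")
      manifest$artifacts[[tg]]["thresholds"] <- file.path(tdir, "thresholds.json")
      manifest$artifacts[[tg]]["metrics"] <- file.path(tdir, "metrics.json")
    }

    ints <- study$interactions[[tg]]
    if (!is.null(ints) && length(ints) >= 2) {
      consensus_ints <- suppressWarnings(
        merge_consensus_interactions(ints[[1]], ints[[2]])
      )
      all_ligs <- tbl$ligand_id
      fp <- build_fingerprint_matrix(consensus_ints, ligand_ids = all_ligs)
      sim <- tanimoto_matrix(fp)
      hc <- cluster_fingerprints(sim, linkage = cfg$linkage)
      write_fingerprints(fp, file.path(tdir, "fingerprints.csv"))
      write_similarity(sim, file.path(tdir, "similarity.csv"))
      write_dendrogram_json(hc, file.path(tdir, "dendrogram.json"))
      manifest$artifacts[[tg]]["fingerprints"] <- file.path(tdir, "fingerprints.csv")
      manifest$artifacts[[tg]]["similarity"] <- file.path(tdir, "similarity.csv")
      manifest$artifacts[[tg]]["dendrogram"] <- file.path(tdir, "dendrogram.json")
    }
  }

  if (!is.null(study$activities) && nrow(study$activities) >= 3) {
    tg <- cfg$activity_target
    tbl <- study$scores[[tg]]
    ranks <- relative_ranks(tbl, study$specs, missing_policy = cfg$missing_policy)
    cons <- consensus_rank(ranks, sigma = cfg$sigma, prefactor = cfg$prefactor)
    joined <- dplyr::inner_join(study$activities, cons, by = "ligand_id") |>
      dplyr::inner_join(tbl, by = "ligand_id")
    cors <- list()
    for (v in c("ecr", "aggregated_rank", "borda",
                setdiff(names(tbl), "ligand_id"))) {
      cors[[v]] <- tryCatch(
        as.list(rank_correlation(joined[c("ligand_id", v, "pIC50")],
                                 !!rlang::sym(v), .data$pIC50)),
        error = function(e) list(error = conditionMessage(e))
      )
    }
    jsonlite::write_json(cors, file.path(cfg$out_dir, "correlations.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    manifest$artifacts$correlations <- file.path(cfg$out_dir, "correlations.json")
  }

  jsonlite::write_json(manifest, file.path(cfg$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}
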