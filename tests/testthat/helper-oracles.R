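# Independent oracles and fixture builders shared across tests.

# Metrics oracle: reconstructs explicit label vectors from confusion counts
# and computes MCC as the Pearson correlation of the 0/1 label vectors and
# BAC from tabulated recalls -- a different computational path than the
# package's closed-form counts.
oracle_metrics <- function(tp, fp, fn, tn) {
  truth <- c(rep(1, tp + fn), rep(0, fp + tn))
  pred <- c(rep(1, tp), rep(0, fn), rep(1, fp), rep(0, tn))
  mcc <- suppressWarnings(stats::cor(truth, pred))
  if (is.na(mcc)) mcc <- 0
  r_pos <- if (tp + fn > 0) mean(pred[truth == 1] == 1) else NA_real_
  r_neg <- if (fp + tn > 0) mean(pred[truth == 0] == 0) else NA_real_
  list(mcc = mcc, bac = (r_pos + r_neg) / 2)
}

# All 2x2 confusion tables with fixed class margins (actual positives p,
# actual negatives n).
enumerate_tables <- function(p, n) {
  grid <- expand.grid(tp = 0:p, fp = 0:n)
  grid$fn <- p - grid$tp
  grid$tn <- n - grid$fp
  grid
}

# Brute-force agglomeration on a distance matrix; returns the cophenetic
# distance matrix (height at which each pair first shares a cluster).
oracle_cophenetic <- function(d, linkage = "average") {
  n <- nrow(d)
  clusters <- as.list(seq_len(n))
  coph <- matrix(0, n, n)
  while (length(clusters) > 1) {
    best <- c(Inf, NA, NA)
    for (i in seq_along(clusters)) {
      for (j in seq_along(clusters)) {
        if (j <= i) next
        pair_d <- d[clusters[[i]], clusters[[j]], drop = FALSE]
        dist_ij <- switch(linkage,
          average = mean(pair_d), complete = max(pair_d), single = min(pair_d)
        )
        if (dist_ij < best[1]) best <- c(dist_ij, i, j)
      }
    }
    i <- best[2]; j <- best[3]
    coph[clusters[[i]], clusters[[j]]] <- best[1]
    coph[clusters[[j]], clusters[[i]]] <- best[1]
    clusters[[i]] <- c(clusters[[i]], clusters[[j]])
    clusters[[j]] <- NULL
  }
  coph
}

# Spearman via the classical d^2 formula (valid without ties).
oracle_spearman <- function(x, y) {
  d <- rank(x) - rank(y)
  n <- length(x)
  1 - 6 * sum(d^2) / (n * (n^2 - 1))
}

# Analytic score-density crossing of two Gaussians, root between the means.
gaussian_crossing <- function(m1, s1, m2, s2) {
  stats::uniroot(function(x) stats::dnorm(x, m1, s1) - stats::dnorm(x, m2, s2),
                 interval = c(m1, m2))$root
}

# Minimal PLIP-style XML report written to a temp file.
write_plip_xml <- function(groups) {
  lines <- c("<report>", "  <bindingsite id=\"1\">", "    <interactions>")
  for (g in names(groups)) {
    lines <- c(lines, paste0("      <", g, "s>"))
    for (row in groups[[g]]) {
      lines <- c(lines,
        paste0("        <", g, " id=\"1\">",
               "<resnr>", row$resnr, "</resnr>",
               "<restype>", row$restype, "</restype>",
               "<reschain>", row$reschain, "</reschain>",
               "<dist>3.51</dist>",
               "</", g, ">"))
    }
    lines <- c(lines, paste0("      </", g, "s>"))
  }
  lines <- c(lines, "    </interactions>", "  </bindingsite>", "</report>")
  path <- withr::local_tempfile(fileext = ".xml",
                                .local_envir = parent.frame())
  writeLines(lines, path)
  path
}

# Published two-ligand score table for the E/Z geometric isomer pair and
# its 11-function direction metadata (packaged fixtures).
load_isomer_fixture <- function() {
  specs <- read_function_specs(
    system.file("extdata", "ci_scoring_functions.csv", package = "dockconsensus")
  )
  table <- read_score_table(
    system.file("extdata", "fenpyroximate_ci_scores.csv", package = "dockconsensus"),
    specs, target_id = "CI"
  )
  list(specs = specs, table = table)
}

make_records <- function(ligand_id, program, keys) {
  parts <- strsplit(keys, "@", fixed = TRUE)
  tibble::tibble(
    interaction_type = vapply(parts, `[[`, "", 1),
    residue_number = as.integer(vapply(parts, `[[`, "", 2)),
    residue_type = vapply(parts, `[[`, "", 3),
    chain = vapply(parts, `[[`, "", 4),
    ligand_id = ligand_id,
    program = program
  )
}
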