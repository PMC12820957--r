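two_fn_specs <- function() {
  scoring_functions(c("lo", "hi"), c("p1", "p2"),
                    c("lower_is_better", "higher_is_better"))
}

test_that("relative ranks honor ranking direction", {
  specs <- two_fn_specs()
  tbl <- tibble::tibble(ligand_id = c("E", "Z"),
                        lo = c(-9.14, -8.70), hi = c(86.32, 80.59))
  r <- relative_ranks(tbl, specs)
  get <- function(fn, lig) r$rank[r$function_name == fn & r$ligand_id == lig]
  expect_equal(get("lo", "E"), 1)
  expect_equal(get("lo", "Z"), 2)
  expect_equal(get("hi", "E"), 1)
  expect_equal(get("hi", "Z"), 2)
})

test_that("ties receive average ranks and missing scores follow the policy", {
  specs <- scoring_functions("f", "p", "lower_is_better")
  tbl <- tibble::tibble(ligand_id = c("A", "B", "C"), f = c(5, 5, 1))
  r <- relative_ranks(tbl, specs)
  expect_equal(r$rank[match(c("C", "A", "B"), r$ligand_id)], c(1, 2.5, 2.5))

  tbl2 <- tibble::tibble(ligand_id = c("A", "B"), f = c(3, NA))
  worst <- relative_ranks(tbl2, specs, missing_policy = "worst_rank")
  expect_equal(worst$rank[match(c("A", "B"), worst$ligand_id)], c(1, 2))
  expect_equal(unique(worst$n_ranked), 1)

  omitted <- relative_ranks(tbl2, specs, missing_policy = "omit")
  expect_false("B" %in% omitted$ligand_id)
})

test_that("ranks are a permutation of 1..n without ties or missing values", {
  specs <- two_fn_specs()
  for (seed in 1:5) {
    tbl <- withr::with_seed(seed, tibble::tibble(
      ligand_id = paste0("l", 1:12), lo = rnorm(12), hi = rnorm(12)
    ))
    r <- relative_ranks(tbl, specs)
    for (fn in c("lo", "hi")) {
      expect_setequal(r$rank[r$function_name == fn], 1:12)
    }
  }
})

test_that("Borda sums and aggregated ranks match the isomer worked example", {
  fx <- load_isomer_fixture()
  # Oracle: per-function pairwise preference over the 11 printed score
  # pairs under the footnote directions, independent of relative_ranks().
  wins_e <- 0
  for (fn in fx$specs$name) {
    s <- fx$table[[fn]]
    better_low <- fx$specs$direction[fx$specs$name == fn] == "lower_is_better"
    if ((better_low && s[1] < s[2]) || (!better_low && s[1] > s[2])) {
      wins_e <- wins_e + 1
    }
  }
  expect_equal(wins_e, 9)

  cons <- borda_aggregate(relative_ranks(fx$table, fx$specs))
  expect_equal(cons$borda[cons$ligand_id == "E-FPM"], wins_e * 1 + (11 - wins_e) * 2)
  expect_equal(cons$borda[cons$ligand_id == "E-FPM"], 13)
  expect_equal(cons$borda[cons$ligand_id == "Z-FPM"], 20)
  expect_equal(cons$aggregated_rank[cons$ligand_id == "E-FPM"], 1)
  expect_equal(cons$aggregated_rank[cons$ligand_id == "Z-FPM"], 2)
})

test_that("Borda aggregation ties and degenerate cases behave", {
  specs <- scoring_functions(c("f1", "f2"), "p",
                             c("lower_is_better", "lower_is_better"))
  tbl <- tibble::tibble(ligand_id = c("A", "B", "C"),
                        f1 = c(1, 2, 3), f2 = c(2, 1, 3))
  cons <- borda_aggregate(relative_ranks(tbl, specs))
  expect_equal(cons$borda[match(c("A", "B", "C"), cons$ligand_id)], c(3, 3, 6))
  expect_equal(cons$aggregated_rank[match(c("A", "B", "C"), cons$ligand_id)],
               c(1.5, 1.5, 3))

  single <- scoring_functions("f1", "p", "lower_is_better")
  tbl1 <- tibble::tibble(ligand_id = c("A", "B", "C"), f1 = c(2, 1, 3))
  r1 <- relative_ranks(tbl1, single)
  cons1 <- borda_aggregate(r1)
  expect_equal(cons1$aggregated_rank[match(tbl1$ligand_id, cons1$ligand_id)],
               r1$rank[match(tbl1$ligand_id, r1$ligand_id)])

  tbl2 <- tibble::tibble(ligand_id = c("A", "B"), f1 = c(1, NA))
  expect_warning(
    cons2 <- borda_aggregate(relative_ranks(tbl2, single, missing_policy = "omit")),
    "B"
  )
  expect_false("B" %in% cons2$ligand_id)
})

test_that("ECR matches its closed form and the isomer worked example", {
  specs <- scoring_functions("f", "p", "lower_is_better")
  tbl <- tibble::tibble(ligand_id = "A", f = 1)
  one <- ecr_scores(relative_ranks(tbl, specs), sigma = 10)
  expect_equal(one$ecr, 0.1 * exp(-0.1), tolerance = 1e-12)

  fx <- load_isomer_fixture()
  e <- ecr_scores(relative_ranks(fx$table, fx$specs), sigma = 10)
  expect_equal(e$ecr[e$ligand_id == "E-FPM"],
               0.1 * (9 * exp(-0.1) + 2 * exp(-0.2)), tolerance = 1e-12)
  expect_equal(e$ecr[e$ligand_id == "Z-FPM"],
               0.1 * (9 * exp(-0.2) + 2 * exp(-0.1)), tolerance = 1e-12)
  expect_equal(round(e$ecr[e$ligand_id == "E-FPM"], 5), 0.97810)
  expect_equal(round(e$ecr[e$ligand_id == "Z-FPM"], 5), 0.91783)
  expect_gt(e$ecr[e$ligand_id == "E-FPM"], e$ecr[e$ligand_id == "Z-FPM"])

  no_pref <- ecr_scores(relative_ranks(fx$table, fx$specs), prefactor = FALSE)
  expect_equal(no_pref$ecr, e$ecr * 10, tolerance = 1e-12)
  expect_error(ecr_scores(relative_ranks(fx$table, fx$specs), sigma = 0),
               "sigma")
})

test_that("single-function ECR is strictly decreasing in rank and bounded", {
  specs <- scoring_functions("f", "p", "lower_is_better")
  tbl <- tibble::tibble(ligand_id = paste0("l", 1:10), f = 1:10)
  e <- ecr_scores(relative_ranks(tbl, specs), sigma = 10)
  ordered <- e$ecr[match(paste0("l", 1:10), e$ligand_id)]
  expect_true(all(diff(ordered) < 0))
  expect_gt(exp(-0.5), exp(-1.0))
  # with the prefactor, ecr <= n_functions * (1/sigma) * exp(-1/sigma)
  expect_true(all(e$ecr <= (1 / 10) * exp(-1 / 10) + 1e-12))
})

test_that("Borda is invariant to direction-respecting monotone transforms", {
  specs <- two_fn_specs()
  tbl <- withr::with_seed(9, tibble::tibble(
    ligand_id = paste0("l", 1:15), lo = rnorm(15), hi = rnorm(15)
  ))
  base <- borda_aggregate(relative_ranks(tbl, specs))
  warped <- tbl
  warped$lo <- warped$lo^3 + 2 * warped$lo     # strictly increasing
  warped$hi <- exp(warped$hi)                   # strictly increasing
  again <- borda_aggregate(relative_ranks(warped, specs))
  expect_equal(again[order(again$ligand_id), ], base[order(base$ligand_id), ])
})

test_that("ECR and aggregated rank agree exactly under consensus degeneracy", {
  specs <- scoring_functions(c("f1", "f2", "f3"), "p",
                             rep("lower_is_better", 3))
  tbl <- tibble::tibble(ligand_id = paste0("l", 1:8),
                        f1 = 1:8, f2 = (1:8) * 2.5, f3 = (1:8)^2)
  cons <- consensus_rank(relative_ranks(tbl, specs))
  expect_equal(order(cons$aggregated_rank), order(-cons$ecr))
})

test_that("majority vote counts preferences, ties and undecided functions", {
  fx <- load_isomer_fixture()
  vote <- majority_vote_preference(fx$table, fx$specs, "E-FPM", "Z-FPM")
  expect_equal(vote$favors_a, 9)
  expect_equal(vote$favors_b, 2)
  expect_equal(vote$ties, 0)
  expect_equal(vote$undecided, 0)
  expect_equal(vote$favors_a + vote$favors_b + vote$ties + vote$undecided,
               nrow(fx$specs))

  detail <- majority_vote_preference(fx$table, fx$specs, "E-FPM", "Z-FPM",
                                     detail = TRUE)
  expect_equal(sum(detail$vote == "a"), 9)
  expect_setequal(detail$function_name[detail$vote == "b"],
                  c("mbae_del_gold", "mbae_del_glide"))

  specs <- scoring_functions(c("f1", "f2"), "p",
                             c("lower_is_better", "lower_is_better"))
  same <- tibble::tibble(ligand_id = c("A", "B"), f1 = c(1, 1), f2 = c(2, 2))
  expect_equal(majority_vote_preference(same, specs, "A", "B")$ties, 2)

  gap <- tibble::tibble(ligand_id = c("A", "B"), f1 = c(NA, 1), f2 = c(1, 2))
  v <- majority_vote_preference(gap, specs, "A", "B")
  expect_equal(v$undecided, 1)
  expect_error(majority_vote_preference(gap, specs, "A", "nope"), "nope")
})
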