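test_that("preprocessing filters by presence and imputes half-minimum", {
  x <- matrix(2^c(10, 11, 12, 13,
                  10, NA, NA, NA,
                  8, 9, NA, 10), nrow = 3, byrow = TRUE,
              dimnames = list(c("keep", "drop", "impute"), paste0("s", 1:4)))
  pm <- proteome_matrix(x, response = c(0.3, 0.5, 0.6, 0.8))
  prep <- preprocess_proteome(pm, min_presence = 0.7, log2_transform = TRUE)
  expect_setequal(rownames(prep$intensities), c("keep", "impute"))
  # the protein present in 1/4 < 0.7 of samples is dropped
  expect_false("drop" %in% rownames(prep$intensities))
  # imputed entry = log2(0.5 * min observed intensity)
  expect_equal(prep$intensities["impute", "s3"], log2(0.5 * 2^8))
  expect_equal(prep$intensities["keep", ], log2(x["keep", ]))
  expect_true(prep$log2)

  # complete matrix passes through unchanged modulo transform
  pm2 <- tiny_proteome(seed = 2)
  prep2 <- preprocess_proteome(pm2, log2_transform = FALSE)
  expect_identical(prep2$intensities, pm2$intensities)
  expect_error(preprocess_proteome(pm, min_presence = 2))
})

test_that("per-run contribution follows 1 - (a-1)/b with strict bounds", {
  expect_equal(per_run_contribution(1, 5), 1)
  expect_equal(per_run_contribution(5, 5), 1 / 5)
  expect_equal(per_run_contribution(3, 4), 0.5)
  b <- 7
  contrib <- per_run_contribution(1:b, b)
  expect_true(all(diff(contrib) < 0))              # strictly decreasing in rank
  expect_true(all(contrib >= 1 / b & contrib <= 1))
  expect_error(per_run_contribution(0, 3), "1 <= a <= b")
  expect_error(per_run_contribution(4, 3), "1 <= a <= b")
})

fake_run <- function(selected, seed = 1L) {
  structure(list(seed = seed, selected = selected, b = length(selected),
                 rmse_profile = tibble::tibble(size = length(selected),
                                               rmse = 0.1),
                 best_rmse = 0.1, best_size = length(selected)),
            class = "rfe_run")
}

test_that("consensus scores match hand enumeration and run permutation", {
  # protein A: rank 1 of 2 (X = 1), rank 2 of 2 (X = 0.5), absent -> 1.5
  runs <- list(fake_run(c("A", "B")), fake_run(c("B", "A")), fake_run("B"))
  sc <- consensus_scores(runs)
  expect_equal(sc$score[sc$protein_id == "A"], 1.5)
  expect_equal(sc$score[sc$protein_id == "B"], 0.5 + 1 + 1)
  expect_equal(sc$runs_appeared[sc$protein_id == "A"], 2)

  perm <- consensus_scores(runs[c(3, 1, 2)])
  expect_equal(dplyr::arrange(sc, protein_id),
               dplyr::arrange(perm, protein_id))

  # top rank everywhere -> score = n_runs, the maximum
  top <- consensus_scores(replicate(4, fake_run(c("T", "x")),
                                    simplify = FALSE))
  expect_equal(top$score[top$protein_id == "T"], 4)
  expect_true(all(top$score > 0 & top$score <= 4))
})

test_that("finalized signature caps, orders deterministically, and annotates", {
  runs <- list(fake_run(c("A", "B", "C")), fake_run(c("C", "D")))
  sc <- consensus_scores(runs)
  sig <- finalize_signature(sc, cap = 2, n_runs = 2)
  expect_equal(nrow(sig), 2)
  expect_equal(attr(sig, "n_scored"), 4)
  expect_equal(sig$rank, 1:2)
  # C: 1/3 + 1 = 4/3 leads; A: 1
  expect_equal(sig$protein_id[1], "C")

  # equal scores, equal mean contribution -> lexicographic id, stable
  tie_runs <- list(fake_run(c("Z", "Y")), fake_run(c("Y", "Z")))
  s1 <- finalize_signature(consensus_scores(tie_runs), cap = 5, n_runs = 2)
  s2 <- finalize_signature(consensus_scores(tie_runs), cap = 5, n_runs = 2)
  expect_identical(s1$protein_id, c("Y", "Z"))
  expect_identical(s1$protein_id, s2$protein_id)

  expect_error(finalize_signature(consensus_scores(runs), cap = 0), "cap")
})

test_that("direction annotation follows the sign of the Spearman correlation", {
  resp <- c(0.2, 0.4, 0.6, 0.8, 0.5, 0.3)
  x <- rbind(with_resp = resp,            # intensity = response -> poorer
             against = -resp,             # opposite -> better
             const = rep(1, 6))
  colnames(x) <- paste0("s", 1:6)
  pm <- manual_proteome(x, resp)
  d <- annotate_direction(pm, c("with_resp", "against"))
  expect_equal(d$direction, c("poorer", "better"))
  expect_equal(d$rho, c(1, -1))
  expect_error(annotate_direction(pm, "const"), "constant")
  expect_error(annotate_direction(pm, "nope"), "not in matrix")
})

test_that("planted positive-effect proteins are labelled poorer response", {
  agree <- vapply(1:20, function(s) {
    pm <- simulate_proteome(sim_config(seed = s, n_proteins = 80,
                                       n_planted = 8, missing_rate = 0))
    pos <- pm$truth$planted$protein_id[pm$truth$planted$sign > 0]
    d <- annotate_direction(pm, pos)
    mean(d$direction == "poorer")
  }, numeric(1))
  expect_gte(mean(agree), 0.9)
})

test_that("backward elimination recovers planted structure and is deterministic", {
  pm <- tiny_proteome(seed = 8, n_proteins = 40, n_planted = 5)
  prep <- preprocess_proteome(pm)
  r1 <- rfe_run(prep, seed = 11)
  r2 <- rfe_run(prep, seed = 11)
  expect_identical(r1$selected, r2$selected)
  expect_identical(r1$rmse_profile, r2$rmse_profile)
  expect_equal(r1$b, length(r1$selected))
  expect_equal(r1$best_rmse, min(r1$rmse_profile$rmse))
  # argmin property: the chosen subset beats (or ties) the full model
  expect_lte(r1$best_rmse,
             r1$rmse_profile$rmse[r1$rmse_profile$size == nrow(prep$intensities)])

  planted <- pm$truth$planted$protein_id
  expect_gte(mean(r1$selected %in% planted), 0.4)
})

test_that("rfe guards its preconditions", {
  pm <- tiny_proteome(seed = 1, n_proteins = 10, n_planted = 2)
  prep <- preprocess_proteome(pm)
  expect_error(rfe_run(prep, seed = 1, size_schedule = c(50, 10)),
               "exceeds")
  const <- manual_proteome(
    prep$intensities, rep(0.5, ncol(prep$intensities)))
  expect_error(rfe_run(const, seed = 1), "constant response")
  raw <- simulate_proteome(sim_config(seed = 3, n_proteins = 10,
                                      missing_rate = 0.3, n_planted = 2))
  expect_error(rfe_run(raw, seed = 1), "missing")
})

test_that("size schedule halves geometrically down to the fixed tail", {
  expect_equal(default_size_schedule(300),
               c(300L, 150L, 75L, 37L, 18L, 9L, 8L, 6L, 4L, 2L))
  expect_equal(default_size_schedule(8), c(8L, 6L, 4L, 2L))
  expect_equal(default_size_schedule(5), c(5L, 4L, 2L))
})

test_that("exhaustive best-subset search bounds the RFE-chosen RMSE at small p", {
  # brute-force oracle over all non-empty subsets of 6 proteins, using the
  # same LOO-RMSE estimator; RFE cannot beat the best subset by more than
  # resampling noise, and must find the planted protein
  pm <- tiny_proteome(seed = 13, n_proteins = 6, n_planted = 1,
                      effect_size = 2)
  prep <- preprocess_proteome(pm)
  ids <- rownames(prep$intensities)

  loo_rmse <- function(feats, seed) {
    withr::with_seed(seed, clonesig:::.rf_cv_rmse(
      t(prep$intensities[feats, , drop = FALSE]), prep$response,
      "loo", 500))
  }
  subsets <- unlist(lapply(seq_along(ids), function(k)
    utils::combn(ids, k, simplify = FALSE)), recursive = FALSE)
  best_rmse <- min(vapply(subsets, loo_rmse, numeric(1), seed = 99))

  run <- rfe_run(prep, seed = 99)
  expect_lte(best_rmse, run$best_rmse + 0.05)
  expect_true(pm$truth$planted$protein_id %in% run$selected)
})

test_that("ensembles are seeded, sized, and reproducible", {
  pm <- tiny_proteome(seed = 4, n_proteins = 20, n_planted = 3)
  prep <- preprocess_proteome(pm)
  ens <- run_ensemble(prep, n_runs = 3, base_seed = 7)
  expect_length(ens, 3)
  expect_equal(purrr::map_int(ens, "seed"), 8:10)
  ens2 <- run_ensemble(prep, n_runs = 3, base_seed = 7)
  expect_identical(purrr::map(ens, "selected"), purrr::map(ens2, "selected"))
  expect_error(run_ensemble(prep, n_runs = 0), "n_runs")
})

test_that("consensus scores are invariant to protein-row permutation", {
  pm <- tiny_proteome(seed = 6, n_proteins = 20, n_planted = 3)
  prep <- preprocess_proteome(pm)
  perm <- sample(nrow(prep$intensities))
  prep_perm <- proteome_matrix(prep$intensities[perm, ], prep$response,
                               log2 = TRUE)
  sc1 <- consensus_scores(run_ensemble(prep, n_runs = 2, base_seed = 3))
  sc2 <- consensus_scores(run_ensemble(prep_perm, n_runs = 2, base_seed = 3))
  expect_equal(dplyr::arrange(sc1, protein_id),
               dplyr::arrange(sc2, protein_id))
})
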