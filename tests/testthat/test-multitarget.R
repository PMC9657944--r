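test_that("hypergeometric tail probabilities match exact combinatorics", {
  expect_equal(hypergeom_pvalue(24, 10, 5, 0), 1.0)
  expect_equal(hypergeom_pvalue(24, 10, 5, 5), choose(10, 5) / choose(24, 5),
               tolerance = 1e-12)
  expect_equal(hypergeom_pvalue(24, 24, 3, 3), 1.0)
  expect_equal(hypergeom_pvalue(24, 1, 1, 1), 1 / 24, tolerance = 1e-12)
  # all-active-in-one-group case
  expect_equal(hypergeom_pvalue(24, 10, 10, 10), choose(10, 10) / choose(24, 10),
               tolerance = 1e-12)
})

test_that("hypergeometric tail equals brute-force enumeration on small populations", {
  for (N in c(5, 8)) {
    for (K in 0:N) {
      for (n in 0:N) {
        for (k in max(0, n + K - N):min(n, K)) {
          expect_equal(hypergeom_pvalue(N, K, n, k),
                       hyper_tail_bruteforce(N, K, n, k), tolerance = 1e-12)
        }
      }
    }
  }
})

test_that("tail probability is monotone in k and point masses sum to one", {
  for (N in c(10, 24)) {
    K <- 7; n <- 6
    ks <- max(0, n + K - N):min(n, K)
    p <- hypergeom_pvalue(rep(N, length(ks)), K, n, ks)
    expect_true(all(diff(p) <= 1e-14))
    point <- stats::dhyper(ks, K, N - K, n)
    expect_equal(sum(point), 1, tolerance = 1e-12)
  }
})

test_that("inconsistent hypergeometric counts are rejected", {
  expect_error(hypergeom_pvalue(10, 12, 3, 1), "inconsistent")
  expect_error(hypergeom_pvalue(10, 5, 3, 4), "inconsistent")
  expect_error(hypergeom_pvalue(10, 5, 11, 2), "inconsistent")
  expect_error(hypergeom_pvalue(10, 9, 5, 2), "inconsistent")  # k < n+K-N floor
})

# 24-target panel shaped like the epigenetic families
panel_registry <- function() {
  target_registry(
    paste0("P", 1:24),
    c(rep("HDAC", 10), rep("HMT", 6), rep("HDM", 5), rep("HAT", 2), "DNMT")
  )
}

fake_calls <- function(active_targets, registry) {
  tibble::tibble(
    compound_id = "drug1",
    target_id = registry$target_id,
    probability = ifelse(registry$target_id %in% active_targets, 0.9, 0.1),
    call = ifelse(registry$target_id %in% active_targets, "active", "inactive")
  )
}

test_that("group enrichment flags a compound hitting one whole family", {
  reg <- panel_registry()
  calls <- fake_calls(paste0("P", 1:10), reg)  # all 10 HDAC targets, nothing else
  rep <- epitarget:::polypharm_from_calls(calls, reg, alpha = 0.05)
  hd <- rep[rep$object_group == "HDAC", ]
  expect_equal(hd$k, 10); expect_equal(hd$K, 10); expect_equal(hd$n, 10)
  expect_equal(hd$p_value, choose(10, 10) / choose(24, 10), tolerance = 1e-12)
  expect_true(hd$significant)
  expect_false(any(rep$significant[rep$object_group != "HDAC"]))
})

test_that("a compound with no active calls reports p = 1 everywhere", {
  reg <- panel_registry()
  rep <- epitarget:::polypharm_from_calls(fake_calls(character(0), reg), reg)
  expect_true(all(rep$p_value == 1))
  expect_false(any(rep$significant))
})

test_that("a singleton family called active alone is significant at 1/24", {
  reg <- panel_registry()
  rep <- epitarget:::polypharm_from_calls(fake_calls("P24", reg), reg)  # DNMT
  dn <- rep[rep$object_group == "DNMT", ]
  expect_equal(dn$p_value, 1 / 24, tolerance = 1e-12)
  expect_true(dn$significant)
  # Bonferroni across the 5 families pushes it over alpha
  rep_b <- epitarget:::polypharm_from_calls(fake_calls("P24", reg), reg,
                                            correct = "bonferroni")
  expect_false(rep_b$significant[rep_b$object_group == "DNMT"])
})

test_that("multi-target assembly equals the single-target classifiers exactly", {
  fx <- make_multilabel_fixture(n_targets = 2, overlap = 0.5, seed = 9,
                                n_molecules = 80, unknown_fraction = 0)
  mt <- fit_multitarget(fx$records, fx$registry, tiny_encoder("gcn"),
                        booster_config(n_trees = 30))
  mols <- dplyr::distinct(fx$records, compound_id, smiles)[1:15, ]
  pred <- predict_multitarget(mt, mols)
  graphs <- smiles_to_graphs(mols$smiles, mt$scheme, ids = mols$compound_id)
  for (tid in fx$registry$target_id) {
    single <- predict(mt$models[[tid]]$classifier,
                      embed(mt$models[[tid]]$encoder, graphs))
    got <- pred[pred$target_id == tid, ]
    expect_identical(got$probability[match(mols$compound_id, got$compound_id)],
                     single$probability)
  }
  # column (target) order follows the registry; a molecule in two batches
  # gets identical rows
  expect_equal(unique(pred$target_id), fx$registry$target_id)
  pred_one <- predict_multitarget(mt, mols[3, ])
  expect_identical(pred_one$probability,
                   pred$probability[pred$compound_id == mols$compound_id[3]])
})

test_that("unparseable molecules are reported while others are still predicted", {
  fx <- make_multilabel_fixture(n_targets = 2, overlap = 0.5, seed = 9,
                                n_molecules = 80, unknown_fraction = 0)
  mt <- fit_multitarget(fx$records, fx$registry, tiny_encoder("gcn"),
                        booster_config(n_trees = 30))
  bad <- tibble::tibble(compound_id = c("ok", "broken"),
                        smiles = c("CCO", "xx(("))
  pred <- predict_multitarget(mt, bad)
  expect_equal(unique(pred$compound_id), "ok")
  expect_equal(attr(pred, "failures")$id, "broken")
})

test_that("model archives round-trip and refuse corruption", {
  fx <- make_multilabel_fixture(n_targets = 2, overlap = 0.5, seed = 19,
                                n_molecules = 60, unknown_fraction = 0)
  mt <- fit_multitarget(fx$records, fx$registry, tiny_encoder("gcn"),
                        booster_config(n_trees = 20))
  dir <- withr::local_tempdir()
  save_multitarget(mt, dir)
  mt2 <- load_multitarget(dir)
  mols <- dplyr::distinct(fx$records, compound_id, smiles)[1:5, ]
  expect_identical(predict_multitarget(mt, mols)$probability,
                   predict_multitarget(mt2, mols)$probability)
  # corrupt the manifest fingerprint
  mf <- jsonlite::read_json(file.path(dir, "manifest.json"))
  mf$scheme_fingerprint <- "tampered"
  jsonlite::write_json(mf, file.path(dir, "manifest.json"), auto_unbox = TRUE)
  expect_error(load_multitarget(dir), "does not match")
  expect_error(load_multitarget(withr::local_tempdir()), "manifest")
})

test_that("polypharmacology report needs at least two object groups", {
  fx <- make_multilabel_fixture(n_targets = 2, overlap = 0.5, seed = 19,
                                n_molecules = 60, unknown_fraction = 0)
  mt <- fit_multitarget(fx$records, fx$registry, tiny_encoder("gcn"),
                        booster_config(n_trees = 20))
  mt$registry$object_group <- "HDAC"
  expect_error(polypharmacology_report(mt, tibble::tibble(compound_id = "a", smiles = "CCO")),
               "2 object groups")
})
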