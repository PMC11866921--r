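test_that("aggregation unions sources and merges stereoisomers", {
  a <- suspect_list(data.frame(suspect_id = "a1", parent_id = "P",
                               kind = "structure", smiles = "Nc1ccccc1",
                               formula = NA, sources = "BTE", label = "x"))
  b <- suspect_list(data.frame(suspect_id = "b1", parent_id = "P",
                               kind = "structure", smiles = "C1=CC=CC=C1N",
                               formula = NA, sources = "LIT", label = "x"))
  agg <- aggregate_suspects(list(a, b))
  expect_equal(nrow(agg), 1)
  expect_setequal(strsplit(agg$sources, ";")[[1]], c("BTE", "LIT"))
  # stereoisomers merge under the connectivity key
  s1 <- suspect_list(data.frame(suspect_id = "s1", parent_id = "P",
                                kind = "structure", smiles = "C[C@H](O)CC",
                                formula = NA, sources = "CTS", label = ""))
  s2 <- suspect_list(data.frame(suspect_id = "s2", parent_id = "P",
                                kind = "structure", smiles = "C[C@@H](O)CC",
                                formula = NA, sources = "BTH", label = ""))
  agg2 <- aggregate_suspects(list(s1, s2))
  expect_equal(nrow(agg2), 1)
  # same structure under different parents stays separate
  s3 <- suspect_list(data.frame(suspect_id = "s3", parent_id = "Q",
                                kind = "structure", smiles = "CC(O)CC",
                                formula = NA, sources = "LIT", label = ""))
  agg3 <- aggregate_suspects(list(s1, s3))
  expect_equal(nrow(agg3), 2)
})

test_that("aggregation is idempotent and total on empty input", {
  x <- demo_suspects(seed = 2)
  y <- aggregate_suspects(x)
  expect_equal(nrow(y), nrow(x))
  expect_identical(sort(y$sources), sort(x$sources))
  empty <- aggregate_suspects(list())
  expect_equal(nrow(empty), 0)
})

test_that("metabolic logic generates feasible formula suspects only", {
  met <- structure_record("MET", "CC(C)NCC(O)COc1ccc(CCOC)cc1")
  out <- logic_formula_suspects(met)
  expect_true("C15H27NO5" %in% out$formula)   # + H2O2
  expect_true(all(out$kind == "formula"))
  expect_true(all(out$sources == "LOGIC"))
  # infeasible delta (no fluorine in the parent) is skipped with a reason
  expect_false(any(grepl("C2HF3", out$label) & grepl("-", out$label)))
  expect_true(any(grepl("C2HF3", attr(out, "skipped"))))
  phe <- structure_record("PHE", "CC1=CC(=O)N(c2ccccc2)N1C")
  out2 <- logic_formula_suspects(phe, list(
    list(add = NULL, sub = "F", label = "-F"),
    list(add = "O", sub = NULL, label = "+O"),
    list(add = NULL, sub = "H2", label = "-H2")))
  expect_equal(nrow(out2), 2)               # -F skipped
  expect_length(attr(out2, "skipped"), 1)
  expect_equal(length(unique(out2$formula)), 2)
})

test_that("m/z matching respects tolerance and structure precedence", {
  des <- experiment_design(data.frame(
    sample_id = c("s0", "s2"), type = "mixture", condition = "U",
    exposure_h = c(0, 2), replicate = 1, conc_A = 150))
  ft <- feature_table(data.frame(
    group_id = c("hit", "miss", "both"),
    mz = c(94.0650, 94.0720, 127.0502), rt = 1, s0 = 0, s2 = 1e4), des)
  sus <- suspect_list(data.frame(
    suspect_id = c("ani", "fs", "ss"), parent_id = "A",
    kind = c("structure", "formula", "structure"),
    smiles = c("Nc1ccccc1", NA, "Cc1onc(N)c1N"),     # last: C4H7N3O? no.
    formula = c(NA, "C5H6N2O2", NA),
    sources = "LIT", label = ""))
  res <- match_suspects(ft, sus)
  expect_true(any(res$matches$group_id == "hit" &
                    res$matches$suspect_id == "ani"))
  expect_false("miss" %in% res$matches$group_id)   # 6.9 mDa away
  cls <- setNames(res$classes$class, res$classes$group_id)
  expect_equal(cls[["hit"]], "structure")
  expect_equal(cls[["miss"]], "unknown")
})

test_that("structure matches pre-empt formula matches on the same feature", {
  des <- experiment_design(data.frame(
    sample_id = c("s0", "s2"), type = "mixture", condition = "U",
    exposure_h = c(0, 2), replicate = 1, conc_A = 150))
  mz_ani <- adduct_mz("C6H7N")
  ft <- feature_table(data.frame(group_id = "f", mz = mz_ani, rt = 1,
                                 s0 = 0, s2 = 1e4), des)
  sus <- suspect_list(data.frame(
    suspect_id = c("st", "fo"), parent_id = "A",
    kind = c("structure", "formula"),
    smiles = c("Nc1ccccc1", NA), formula = c(NA, "C6H7N"),
    sources = "LIT", label = ""))
  res <- match_suspects(ft, sus)
  expect_identical(unique(res$matches$kind), "structure")
  expect_equal(res$classes$class, "structure")
})

test_that("every prioritized feature lands in exactly one class", {
  sim <- simulate_experiment(demo_simulation_spec(n_noise = 100, seed = 8))
  pr <- prioritize(sim$features, sim$design,
                   parent_groups = paste0("P_", demo_parents()$parent_id))
  res <- match_suspects(pr, demo_suspects(seed = 8))
  expect_equal(nrow(res$classes), nrow(pr))
  expect_true(all(res$classes$class %in% c("structure", "formula", "unknown")))
  tab <- table(res$classes$class)
  expect_equal(sum(tab), nrow(pr))
})
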