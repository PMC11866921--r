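# Design with 3 parents, mixture + single-parent experiments.
link_design <- function() {
  rows <- list()
  add <- function(type, conc) {
    for (e in c(0, 2)) {
      cp <- setNames(rep(conc, 3), paste0("conc_", c("P", "Q", "R")))
      if (grepl("^single:", type)) {
        cp[] <- 0; cp[paste0("conc_", sub("single:", "", type))] <- conc
      }
      rows[[length(rows) + 1L]] <<- c(list(
        sample_id = paste0(gsub(":", "-", type), "_", e, "h"), type = type,
        condition = "U", exposure_h = e, replicate = 1), as.list(cp))
    }
  }
  add("mixture", 150)
  for (p in c("P", "Q", "R")) add(paste0("single:", p), 150)
  experiment_design(do.call(rbind.data.frame, c(rows, stringsAsFactors = FALSE)))
}

link_features <- function(design, mix, own, q, r) {
  v <- setNames(rep(0, nrow(design)), design$sample_id)
  v["mixture_2h"] <- mix
  v["single-P_2h"] <- own
  v["single-Q_2h"] <- q
  v["single-R_2h"] <- r
  df <- data.frame(group_id = "f", mz = 100, rt = 1)
  df[names(v)] <- as.list(v)
  feature_table(df, design)
}

test_that("provisional links follow suspect matches and mixture presence", {
  des <- link_design()
  ft <- link_features(des, mix = 1000, own = 0, q = 0, r = 0)
  matches <- data.frame(group_id = "f", suspect_id = "s1", parent_id = "P",
                        kind = "structure", mz_error_mda = 0.1)
  l1 <- build_links(matches, character(0), ft, des)
  expect_equal(nrow(l1), 1)
  expect_equal(l1$candidate_ref, "s1")
  # unknown feature links provisionally to every parent
  l2 <- build_links(matches[0, ], "f", ft, des)
  expect_equal(nrow(l2), 3)
  expect_setequal(l2$parent_id, c("P", "Q", "R"))
  # feature absent from every mixture sample: no links
  ft0 <- link_features(des, mix = 0, own = 0, q = 500, r = 0)
  l3 <- build_links(matches[0, ], "f", ft0, des)
  expect_equal(nrow(l3), 0)
})

test_that("the 5x single-parent rule prunes as specified", {
  des <- link_design()
  run <- function(mix, own, q) {
    ft <- link_features(des, mix, own, q, r = 0)
    links <- data.frame(parent_id = "P", group_id = "f",
                        candidate_ref = "unknown", status = "kept")
    prune_links(links, ft, des)$status
  }
  expect_equal(run(600, 0, 100), "kept")               # ratio 6 >= 5
  expect_match(run(600, 0, 200), "removed")            # ratio 3
  expect_equal(run(600, 50, 200), "kept")              # own-parent clause
  expect_equal(run(600, 0, 0), "kept")                 # absent elsewhere
})

test_that("pruning decisions equal the brute-force rule oracle", {
  des <- link_design()
  k <- default_config()$link_intensity_factor
  oracle <- function(mix, own, q, r) {
    for (other in c(q, r)) {
      if (other > 0) {
        if (own > 0) next
        if (mix >= k * other) next
        return("removed")
      }
    }
    "kept"
  }
  grid <- expand.grid(mix = c(0, 100, 499, 500, 1000, 5000),
                      own = c(0, 50), q = c(0, 100, 400), r = c(0, 100))
  for (i in seq_len(nrow(grid))) {
    g <- grid[i, ]
    ft <- link_features(des, g$mix, g$own, g$q, g$r)
    links <- data.frame(parent_id = "P", group_id = "f",
                        candidate_ref = "unknown", status = "kept")
    got <- prune_links(links, ft, des)$status
    want <- oracle(g$mix, g$own, g$q, g$r)
    expect_equal(sub(":.*", "", got), want,
                 label = paste(unlist(g), collapse = "/"))
  }
})

test_that("pruning output is a subset of its input", {
  sim <- simulate_experiment(demo_simulation_spec(n_noise = 50, seed = 31))
  pr <- prioritize(sim$features, sim$design,
                   parent_groups = paste0("P_", demo_parents()$parent_id))
  res <- match_suspects(pr, demo_suspects(seed = 31))
  unknowns <- res$classes$group_id[res$classes$class == "unknown"]
  links <- build_links(res$matches, unknowns, sim$features, sim$design)
  pruned <- prune_links(links, sim$features, sim$design)
  expect_equal(nrow(pruned), nrow(links))
  expect_true(all(pruned$status[links$status != "kept"] != "kept"))
  key <- function(d) paste(d$parent_id, d$group_id, d$candidate_ref)
  expect_setequal(key(pruned), key(links))
})
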