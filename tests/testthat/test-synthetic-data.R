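test_that("generators are fully deterministic under a fixed seed", {
  cfg <- small_config(seed = 11)
  d <- make_design(5, 5, "tr")
  expect_identical(as.data.frame(simulate_counts(cfg, d)),
                   as.data.frame(simulate_counts(cfg, d)))
  expect_identical(as.data.frame(simulate_abundances(cfg, d, "metabolite")),
                   as.data.frame(simulate_abundances(cfg, d, "metabolite")))
  expect_identical(as.data.frame(simulate_phospho_pairs(cfg, d)),
                   as.data.frame(simulate_phospho_pairs(cfg, d)))
  kb1 <- generate_knowledge_base(cfg)
  kb2 <- generate_knowledge_base(cfg)
  expect_equal(kb1$reactions, kb2$reactions)
  expect_equal(kb1$motifs, kb2$motifs)
  # different seed, different draw
  cfg2 <- small_config(seed = 12)
  expect_false(identical(as.data.frame(simulate_counts(cfg2, d)),
                         as.data.frame(simulate_counts(cfg, d))))
})

test_that("an empty planted truth leaves all layers null", {
  cfg <- small_config(seed = 2)
  d <- make_design(6, 6, "tr")
  no_de <- tibble::tibble(feature_id = character(), lfc = numeric())
  tab <- simulate_counts(cfg, d, truth = no_de)
  expect_equal(nrow(attr(tab, "planted")), 0)
  m <- transomix:::table_matrix(tab)
  grp <- transomix:::design_split(d)
  lfc <- log2(rowMeans(m[, grp$case]) + 1) - log2(rowMeans(m[, grp$control]) + 1)
  # no planted effect: empirical fold changes centred at zero
  expect_lt(abs(mean(lfc)), 0.15)

  ph <- simulate_phospho_pairs(cfg, d, truth = no_de)
  pm <- transomix:::table_matrix(ph)
  pairs <- attr(ph, "pairs")
  ratios <- pm[pairs$phospho_id, ] / pm[pairs$total_id, ]
  rl <- log2(rowMeans(ratios[, grp$case]) / rowMeans(ratios[, grp$control]))
  expect_lt(abs(mean(rl)), 0.2)
})

test_that("planted count effects are recovered at the study replicate sizes", {
  cfg <- sim_config(seed = 5, n_genes = 200, n_proteins = 50,
                    n_metabolites = 20, n_tfs = 5, n_reactions = 10)
  d <- make_design(11, 12, "tr")
  truth <- tibble::tibble(
    feature_id = transomix:::make_universe(cfg)$genes, lfc = 2)
  tab <- simulate_counts(cfg, d, truth = truth)
  m <- transomix:::table_matrix(tab)
  grp <- transomix:::design_split(d)
  emp <- log2(rowMeans(m[, grp$case]) / rowMeans(m[, grp$control]))
  expect_lt(abs(mean(emp) - 2), 0.3)
})

test_that("planted abundance effects are recovered", {
  cfg <- sim_config(seed = 6, n_genes = 120, n_proteins = 100,
                    n_metabolites = 20, n_tfs = 5, n_reactions = 10)
  d <- make_design(5, 5, "pro")
  truth <- tibble::tibble(feature_id = sprintf("pr%04d", 1:100), lfc = 1.5)
  tab <- simulate_abundances(cfg, d, "protein", truth = truth)
  m <- transomix:::table_matrix(tab)
  grp <- transomix:::design_split(d)
  emp <- log2(rowMeans(m[, grp$case]) / rowMeans(m[, grp$control]))
  expect_lt(abs(mean(emp) - 1.5), 0.3)
})

test_that("a planted phospho ratio doubling is detected with high power", {
  hits <- 0
  n_rep <- 200
  for (i in seq_len(n_rep)) {
    cfg <- sim_config(seed = 4000 + i, n_genes = 50, n_proteins = 20,
                      n_metabolites = 10, n_tfs = 3, n_reactions = 5,
                      n_phospho_pairs = 14, phospho_cv = 0.15)
    d <- make_design(5, 5, "ph")
    mols <- transomix:::make_universe(cfg)$phospho_molecules
    truth <- tibble::tibble(feature_id = mols[1:3], lfc = 1)
    tab <- simulate_phospho_pairs(cfg, d, truth = truth)
    res <- phospho_ratio_test(tab, d)
    if (res$class[res$feature_id == mols[1]] == "increased") hits <- hits + 1
  }
  expect_gt(hits / n_rep, 0.8)
})

test_that("generated knowledge bases satisfy the structural contracts", {
  cfg <- small_config(seed = 8)
  kb <- generate_knowledge_base(cfg)
  # pathways partition the reactions: every reaction in exactly one here
  membership <- unlist(kb$pathways$reaction_ids)
  expect_setequal(membership, kb$reactions$reaction_id)
  expect_false(any(duplicated(membership)))
  expect_true(all(lengths(kb$reactions$enzyme_ids) >= 1))
  expect_true(all(kb$allosteric$mode %in% c("activator", "inhibitor")))
  # the Foxo1-like inactivating phospho-TF is present
  expect_true("inactivating" %in% kb$kinase_tf$phospho_effect)
})

test_that("planted TF target enrichment hits the configured odds ratio", {
  cfg <- sim_config(seed = 13, n_genes = 2000, n_proteins = 400,
                    n_metabolites = 40, n_tfs = 50, n_active_tfs = 25,
                    n_reactions = 20, tf_target_or = 8)
  universe <- transomix:::make_universe(cfg)
  truth <- transomix:::plant_truth(cfg, universe)
  kb <- generate_knowledge_base(cfg, universe, truth)
  act <- truth$liver$active_tfs
  degs <- truth$liver$transcript
  ors <- vapply(seq_len(nrow(act)), function(i) {
    tf <- act$tf_gene_id[i]
    hot <- setdiff(degs$feature_id[sign(degs$lfc) ==
                                     ifelse(act$direction[i] == "increased",
                                            1, -1)], tf)
    targets <- kb$motifs$target_ids[[match(tf, kb$motifs$tf_gene_id)]]
    cand <- setdiff(universe$genes, tf)
    a <- length(intersect(targets, hot))
    b <- length(setdiff(hot, targets))
    c_ <- length(setdiff(targets, hot))
    d_ <- length(setdiff(cand, union(targets, hot)))
    (a / b) / (c_ / d_)
  }, 0)
  expect_gt(mean(ors), 8 * 0.5)
  expect_lt(mean(ors), 8 * 1.5)
})

test_that("generate_study yields an internally consistent bundle", {
  cfg <- small_config(seed = 21)
  st <- generate_study(cfg)
  # blood is metabolite-only
  expect_identical(names(st$tables$blood), "metabolite")
  # shared metabolite IDs across compartments
  expect_identical(st$tables$liver$metabolite$feature_id,
                   st$tables$muscle$metabolite$feature_id)
  expect_true(all(st$tables$blood$metabolite$feature_id %in%
                    st$tables$liver$metabolite$feature_id))
  # every table passes reader validation against its design
  for (comp in c("liver", "muscle")) {
    for (layer in c("transcript", "protein", "metabolite", "lipid")) {
      expect_silent(transomix:::validate_omics_table(
        st$tables[[comp]][[layer]],
        st$designs[[if (layer == "phospho_pair") "phospho" else layer]]))
    }
  }
  # planted increased/decreased sets disjoint, expected networks reference
  # only generated IDs
  pl <- st$ground_truth$planted$liver
  expect_false(any(pl$transcript$lfc == 0))
  exp_net <- st$ground_truth$expected_networks$liver
  ids <- exp_net$nodes$id
  known <- c(st$tables$liver$transcript$feature_id,
             st$tables$liver$protein$feature_id,
             st$tables$liver$metabolite$feature_id,
             st$tables$liver$phospho$feature_id,
             st$kb$reactions$reaction_id)
  expect_true(all(ids %in% known))
})

test_that("blood fold changes correlate with the organ at the target level", {
  rs <- vapply(1:30, function(i) {
    cfg <- sim_config(seed = 6000 + i, n_genes = 150, n_proteins = 60,
                      n_metabolites = 120, n_tfs = 6, n_reactions = 15,
                      blood_cor = 0.4)
    universe <- transomix:::make_universe(cfg)
    truth <- transomix:::plant_truth(cfg, universe)
    organ <- truth$liver$metabolite
    blood <- truth$blood$metabolite
    shared <- intersect(organ$feature_id, blood$feature_id)
    cor(organ$lfc[match(shared, organ$feature_id)],
        blood$lfc[match(shared, blood$feature_id)])
  }, 0)
  expect_gt(mean(rs), 0.2)
  expect_lt(mean(rs), 0.65)
})
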