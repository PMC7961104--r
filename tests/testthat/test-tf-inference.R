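test_that("motif enrichment p-values follow the hypergeometric tail", {
  motifs <- tibble::tibble(tf_gene_id = c("T1", "T2"),
                           motif_id = c("M1", "M2"),
                           target_ids = list(paste0("g", 1:10),
                                             paste0("h", 1:5)))
  background <- c(paste0("g", 1:10), paste0("h", 1:5), paste0("x", 1:85))
  # DEG set exactly one motif's 10 targets
  res <- motif_enrichment(paste0("g", 1:10), background, motifs)
  expect_lt(res$p[res$motif_id == "M1"], 1e-10)
  # disjoint targets, k = 0 -> p = 1
  expect_equal(res$p[res$motif_id == "M2"], 1)
  # brute-force tail summation agrees
  k <- 10; K <- 10; N <- 100; n <- 10
  brute <- sum(dhyper(k:min(K, n), K, N - K, n))
  expect_equal(res$p[res$motif_id == "M1"], brute, tolerance = 1e-12)
  # growing the background with non-target genes can only decrease p
  res2 <- motif_enrichment(paste0("g", 1:10),
                           c(background, paste0("y", 1:100)), motifs)
  expect_lte(res2$p[res2$motif_id == "M1"], res$p[res$motif_id == "M1"])
  # empty DEG set -> all p = 1
  res3 <- motif_enrichment(character(), background, motifs)
  expect_true(all(res3$p == 1))
  # motif with no background targets skipped with a warning
  m2 <- dplyr::bind_rows(motifs, tibble::tibble(
    tf_gene_id = "T3", motif_id = "M3", target_ids = list("zzz")))
  expect_warning(res4 <- motif_enrichment(paste0("g", 1:3), background, m2),
                 "M3")
  expect_false("M3" %in% res4$motif_id)
  expect_error(motif_enrichment("nope", background, motifs), "subset")
})

test_that("enrichment p equals brute-force tail summation on random cases", {
  set.seed(99)
  for (i in 1:50) {
    N <- sample(10:50, 1)
    background <- paste0("g", seq_len(N))
    targets <- sample(background, sample(1:N, 1))
    degs <- sample(background, sample(1:N, 1))
    motifs <- tibble::tibble(tf_gene_id = "T", motif_id = "M",
                             target_ids = list(targets))
    p <- motif_enrichment(degs, background, motifs)$p
    k <- length(intersect(targets, degs))
    brute <- sum(dhyper(k:min(length(targets), length(degs)),
                        length(targets), N - length(targets), length(degs)))
    expect_equal(p, brute, tolerance = 1e-12)
  }
})

test_that("DETF identification needs both motif enrichment and DEG status", {
  enr <- tibble::tibble(tf_gene_id = c("T1", "T2", "T3"),
                        motif_id = c("M1", "M2", "M3"),
                        n_targets = 10, k = 5,
                        p = c(0.001, 0.001, 0.5),
                        q = c(0.003, 0.003, 0.5))
  degs <- make_diff(c("T1", "T2", "T3", "gX"),
                    c("increased", "unchanged", "increased", "decreased"),
                    "transcript")
  got <- identify_detfs(enr, degs, "increased_degs")
  # enriched motif but unchanged TF gene (T2) excluded; non-enriched motif
  # with DEG TF gene (T3) excluded
  expect_identical(got$tf_gene_id, "T1")
  expect_identical(got$activity_change, "increased")
  expect_identical(got$origin, "DETF")
})

test_that("DPTF activity inverts under inactivating phosphorylation", {
  kt <- tibble::tibble(kinase_id = c("Akt", "Erk"),
                       tf_id = c("Foxo1", "Elk1"),
                       phospho_effect = c("inactivating", "activating"))
  enr <- tibble::tibble(tf_gene_id = c("Foxo1", "Elk1"),
                        motif_id = c("MF", "ME"), n_targets = 10, k = 6,
                        p = 0.001, q = 0.004)
  dpps <- make_diff(c("Foxo1", "Elk1"), c("increased", "increased"),
                    "phospho_pair")
  got <- identify_dptfs(dpps, kt, enr, "decreased_degs")
  expect_identical(got$activity_change[got$tf_gene_id == "Foxo1"],
                   "decreased")
  expect_identical(got$activity_change[got$tf_gene_id == "Elk1"],
                   "increased")
  # unchanged phospho is not a DPTF
  dpps2 <- make_diff("Foxo1", "unchanged", "phospho_pair")
  expect_equal(nrow(identify_dptfs(dpps2, kt, enr, "decreased_degs")), 0)
  # unknown phospho effect excluded with warning
  kt_bad <- tibble::tibble(kinase_id = "Akt", tf_id = "Foxo1",
                           phospho_effect = "mystery")
  expect_warning(out <- identify_dptfs(dpps, kt_bad, enr, "decreased_degs"),
                 "Foxo1")
  expect_equal(nrow(out), 0)
})

test_that("kinase-TF edges require a table pair, a DPP and a DRTF", {
  kt <- tibble::tibble(kinase_id = "Akt", tf_id = "Foxo1",
                       phospho_effect = "inactivating")
  dpps <- make_diff(c("Akt", "S6k"), c("increased", "increased"),
                    "phospho_pair")
  drtfs <- tibble::tibble(tf_gene_id = "Foxo1", origin = "DPTF",
                          activity_change = "decreased",
                          enriched_in = "decreased_degs",
                          enrichment_p = 0.001, enrichment_q = 0.004)
  got <- kinase_tf_edges(dpps, drtfs, kt)
  expect_equal(nrow(got), 1)
  expect_identical(got$source, "Akt")
  expect_identical(got$target, "Foxo1")
  expect_identical(got$sign, "activating")  # increased DPP, activation mode
  # pair absent from the table -> no edge
  got2 <- kinase_tf_edges(dpps, drtfs,
                          tibble::tibble(kinase_id = "Erk", tf_id = "Foxo1",
                                         phospho_effect = "activating"))
  expect_equal(nrow(got2), 0)
  # kinase not differentially phosphorylated -> no edge
  dpps3 <- make_diff("Akt", "unchanged", "phospho_pair")
  expect_equal(nrow(kinase_tf_edges(dpps3, drtfs, kt)), 0)
})

test_that("planted active TFs are recovered from planted DEG sets", {
  sens_num <- 0; sens_den <- 0; false_num <- 0; false_den <- 0
  for (i in 1:10) {
    cfg <- sim_config(seed = 800 + i, n_genes = 800, n_proteins = 200,
                      n_metabolites = 30, n_tfs = 20, n_active_tfs = 6,
                      n_reactions = 20, tf_target_or = 8)
    universe <- transomix:::make_universe(cfg)
    truth <- transomix:::plant_truth(cfg, universe)
    kb <- generate_knowledge_base(cfg, universe, truth)
    degs <- diff_from_truth(truth$liver$transcript, "transcript")
    up <- degs$feature_id[degs$class == "increased"]
    down <- degs$feature_id[degs$class == "decreased"]
    detfs <- dplyr::bind_rows(
      identify_detfs(motif_enrichment(up, universe$genes, kb$motifs),
                     degs, "increased_degs"),
      identify_detfs(motif_enrichment(down, universe$genes, kb$motifs),
                     degs, "decreased_degs"))
    act <- truth$liver$active_tfs
    hits <- detfs |>
      dplyr::inner_join(act, by = "tf_gene_id") |>
      dplyr::filter(.data$activity_change == .data$direction)
    sens_num <- sens_num + length(unique(hits$tf_gene_id))
    sens_den <- sens_den + nrow(act)
    false_num <- false_num +
      length(setdiff(unique(detfs$tf_gene_id), act$tf_gene_id))
    false_den <- false_den + (cfg$n_tfs - nrow(act))
  }
  expect_gte(sens_num / sens_den, 0.9)
  expect_lte(false_num / false_den, 0.1)
})
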