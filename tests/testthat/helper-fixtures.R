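# Shared fixtures, all built in code at test time.

# A minimal hand-written knowledge base: 5 reactions, 3 pathways, 2 TFs.
tiny_kb <- function() {
  suppressWarnings(knowledge_base(
    reactions = tibble::tibble(
      reaction_id = paste0("R", 1:5),
      enzyme_ids = list("E1", "E1", "E2", "E3", c("E2", "E4")),
      substrate_ids = list("S1", "S2", "S1", "S3", "S4"),
      product_ids = list("P1", "P2", "P3", c("P1", "P4"), "P5"),
      reversible = c(FALSE, TRUE, FALSE, FALSE, TRUE),
      pathway_ids = list("pw1", "pw1", "pw2", "pw2", "pw3")),
    allosteric = tibble::tibble(
      metabolite_id = c("A1", "A1", "A2"),
      enzyme_protein_id = c("E1", "E2", "E1"),
      mode = c("activator", "inhibitor", "inhibitor")),
    motifs = tibble::tibble(
      tf_gene_id = c("T1", "T2"),
      motif_id = c("M1", "M2"),
      target_ids = list(c("gE1", "gE2"), c("gE3", "gX"))),
    kinase_tf = tibble::tibble(
      kinase_id = c("Aktl", "Erkl"), tf_id = c("T1", "T2"),
      phospho_effect = c("inactivating", "activating")),
    gene_protein_map = tibble::tibble(
      gene_id = c("gE1", "gE2", "gE3", "gE4", "gX"),
      protein_id = c("E1", "E2", "E3", "E4", "PX")),
    metabolite_class = tibble::tibble(
      metabolite_id = c("S1", "S2", "A1", "A2"),
      class = c("carbohydrate", "carbohydrate", "cofactor", "amino_acid")),
    pathways = tibble::tibble(
      pathway_id = c("pw1", "pw2", "pw3"),
      class = c("carbohydrate", "amino_acid", "lipid"),
      reaction_ids = list(c("R1", "R2"), c("R3", "R4"), "R5"))))
}

# diff-result tibble straight from a planted-truth table (everything listed
# is called at q = 0.01, everything else is omitted)
diff_from_truth <- function(truth_tbl, layer, compartment = "liver") {
  tibble::tibble(
    feature_id = truth_tbl$feature_id,
    layer = layer,
    compartment = compartment,
    log2fc = truth_tbl$lfc,
    stat = NA_real_, df = NA_real_, p = 0.001, q = 0.01,
    class = ifelse(truth_tbl$lfc > 0, "increased", "decreased"))
}

# hand-assembled diff rows
make_diff <- function(ids, classes, layer, compartment = "liver",
                      log2fc = NULL) {
  if (is.null(log2fc))
    log2fc <- ifelse(classes == "increased", 1,
                     ifelse(classes == "decreased", -1, 0))
  tibble::tibble(feature_id = ids, layer = layer, compartment = compartment,
                 log2fc = log2fc, stat = NA_real_, df = NA_real_,
                 p = ifelse(classes == "unchanged", 0.8, 0.001),
                 q = ifelse(classes == "unchanged", 0.9, 0.01),
                 class = classes)
}

# run the pipeline's edge constructors + network builder on a planted truth
# (the counterpart the brute-force oracle is compared against)
pipeline_network_from_truth <- function(truth_comp, kb, compartment,
                                        mass_action_signed = FALSE,
                                        fold_mixed = FALSE) {
  degs <- diff_from_truth(truth_comp$transcript, "transcript", compartment)
  deps <- diff_from_truth(truth_comp$protein, "protein", compartment)
  dems <- diff_from_truth(truth_comp$metabolite, "metabolite", compartment)
  dpps <- diff_from_truth(truth_comp$phospho, "phospho_pair", compartment)
  drtfs <- tibble::tibble(
    tf_gene_id = truth_comp$active_tfs$tf_gene_id,
    origin = "DETF",
    activity_change = truth_comp$active_tfs$direction,
    enriched_in = "increased_degs",
    enrichment_p = 0.001, enrichment_q = 0.001)
  edges <- dplyr::bind_rows(
    kinase_tf_edges(dpps, drtfs, kb$kinase_tf),
    tf_gene_edges(drtfs, degs, kb),
    gene_protein_edges(degs, deps, kb$gene_protein_map),
    enzyme_reaction_edges(deps, kb),
    suppressWarnings(allosteric_edges(dems, kb)),
    mass_action_edges(dems, kb))
  build_network(list(transcript = degs, protein = deps, metabolite = dems,
                     phospho = dpps),
                drtfs, edges, kb, compartment,
                mass_action_signed = mass_action_signed,
                fold_mixed = fold_mixed)
}

# order-independent network comparison
expect_same_network <- function(a, b) {
  sort_all <- function(df) df[do.call(order, as.list(df)), , drop = FALSE]
  expect_equal(sort_all(as.data.frame(a$nodes)),
               sort_all(as.data.frame(b$nodes)),
               ignore_attr = TRUE)
  expect_equal(sort_all(as.data.frame(a$edges)),
               sort_all(as.data.frame(b$edges)),
               ignore_attr = TRUE)
  expect_equal(sort_all(as.data.frame(a$reaction_class)),
               sort_all(as.data.frame(b$reaction_class)),
               ignore_attr = TRUE)
}

# small sim config for fast structural tests
small_config <- function(seed = 1, ...) {
  sim_config(seed = seed, n_genes = 120, n_proteins = 60,
             n_metabolites = 30, n_lipids = 8, n_tfs = 8, n_reactions = 25,
             n_pathways = 3, n_active_tfs = 3, n_phospho_pairs = 6,
             replicates = list(transcript = c(5, 5), protein = c(5, 5),
                               metabolite = c(5, 5), lipid = c(3, 3),
                               phospho = c(5, 5)), ...)
}
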