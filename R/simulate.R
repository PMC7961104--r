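#' Configuration for synthetic two-condition multi-omic studies
#'
#' Defaults mirror the fasted lean-vs-obese mouse study design the package
#' emulates: 11 control vs 12 case transcriptome replicates, 5 vs 5 for
#' proteome, metabolome and phospho western blots, 3 vs 3 for lipidome; a
#' planted effect-size magnitude |log2FC| ~ Uniform(0.5, 2); gene-to-protein
#' coupling probability 0.6 for increased and 0.4 for decreased features;
#' and a planted TF target-enrichment odds ratio of 8. The negative-binomial
#' count model uses the mean/dispersion convention with variance
#' \eqn{\mu + \phi\mu^2}.
#'
#' @param seed master seed; every random draw is derived from it.
#' @param n_genes,n_proteins,n_metabolites,n_lipids,n_tfs,n_reactions,n_pathways
#'   universe sizes.
#' @param replicates named list of `c(control, case)` replicate counts per
#'   layer.
#' @param de_fraction fraction of features planted as differential per
#'   layer, in (0, 1).
#' @param effect_range range of planted |log2FC|.
#' @param nb_dispersion negative-binomial dispersion \eqn{\phi} (> 0).
#' @param abundance_cv coefficient of variation of log-normal abundance
#'   layers.
#' @param phospho_cv coefficient of variation of phospho/total signals.
#' @param coupling named probabilities that a planted DEG's protein shares
#'   its change.
#' @param enzyme_fraction fraction of proteins annotated as metabolic
#'   enzymes.
#' @param n_active_tfs planted transcriptionally active TFs per compartment.
#' @param tf_target_or planted odds ratio of motif targets among that TF's
#'   direction of planted DEGs.
#' @param tf_target_base_p baseline probability that a gene is a motif
#'   target.
#' @param n_phospho_pairs number of (phospho, total) western-blot pairs.
#' @param blood_cor target Pearson correlation between blood and organ
#'   metabolite fold changes.
#' @param compartments organ compartments (blood is always added as a
#'   metabolite-only compartment).
#' @return a validated `sim_config` list.
#' @export
sim_config <- function(seed = 1,
                       n_genes = 400, n_proteins = 200, n_metabolites = 60,
                       n_lipids = 14, n_tfs = 15, n_reactions = 40,
                       n_pathways = 4,
                       replicates = list(transcript = c(11, 12),
                                         protein = c(5, 5),
                                         metabolite = c(5, 5),
                                         lipid = c(3, 3),
                                         phospho = c(5, 5)),
                       de_fraction = 0.2,
                       effect_range = c(0.5, 2),
                       nb_dispersion = 0.1,
                       abundance_cv = 0.2,
                       phospho_cv = 0.15,
                       coupling = c(increased = 0.6, decreased = 0.4),
                       enzyme_fraction = 0.5,
                       n_active_tfs = 4,
                       tf_target_or = 8,
                       tf_target_base_p = 0.05,
                       n_phospho_pairs = 14,
                       blood_cor = 0.4,
                       compartments = c("liver", "muscle")) {
  cfg <- as.list(environment())
  counts <- c(cfg$n_genes, cfg$n_proteins, cfg$n_metabolites, cfg$n_lipids,
              cfg$n_tfs, cfg$n_reactions, cfg$n_pathways, cfg$n_phospho_pairs)
  if (any(counts <= 0)) config_error("all universe counts must be positive")
  if (cfg$de_fraction <= 0 || cfg$de_fraction >= 1)
    config_error("de_fraction must lie in (0, 1)")
  if (cfg$nb_dispersion <= 0) config_error("nb_dispersion must be positive")
  if (cfg$enzyme_fraction <= 0 || cfg$enzyme_fraction > 1)
    config_error("enzyme_fraction must lie in (0, 1]")
  if (cfg$n_proteins > cfg$n_genes)
    config_error("more proteins requested than genes to encode them")
  if (cfg$n_tfs + cfg$n_proteins > cfg$n_genes)
    config_error("gene universe too small for TFs plus protein-coding genes")
  structure(cfg, class = "sim_config")
}

#' Build a two-condition sample design
#' @param n_control,n_case replicate counts.
#' @param prefix sample-ID prefix.
#' @return a sample-design tibble.
#' @export
make_design <- function(n_control, n_case, prefix = "s") {
  sample_design(
    c(sprintf("%s_wt%02d", prefix, seq_len(n_control)),
      sprintf("%s_ob%02d", prefix, seq_len(n_case))),
    c(rep("control", n_control), rep("case", n_case)))
}

# Fixed ID universe: genes (protein-coding first, TF genes last), proteins,
# enzymes, metabolites, lipids, phospho molecules.
make_universe <- function(config) {
  genes <- sprintf("g%04d", seq_len(config$n_genes))
  tf_genes <- sprintf("tf%02d", seq_len(config$n_tfs))
  genes[(config$n_genes - config$n_tfs + 1):config$n_genes] <- tf_genes
  proteins <- sprintf("pr%04d", seq_len(config$n_proteins))
  gene_protein_map <- tibble(gene_id = genes[seq_len(config$n_proteins)],
                             protein_id = proteins)
  n_enz <- max(1L, round(config$n_proteins * config$enzyme_fraction))
  phospho <- sprintf("kin%02d", seq_len(config$n_phospho_pairs))
  phospho[config$n_phospho_pairs] <- tf_genes[1]  # the Foxo1-like phospho-TF
  list(genes = genes, tf_genes = tf_genes, proteins = proteins,
       enzymes = proteins[seq_len(n_enz)],
       metabolites = sprintf("m%03d", seq_len(config$n_metabolites)),
       lipids = sprintf("lp%02d", seq_len(config$n_lipids)),
       gene_protein_map = gene_protein_map,
       phospho_molecules = phospho)
}

signed_lfc <- function(n, config) {
  runif(n, config$effect_range[1], config$effect_range[2]) *
    sample(c(-1, 1), n, replace = TRUE)
}

plant_layer <- function(ids, config) {
  n_de <- round(length(ids) * config$de_fraction)
  de <- sample(ids, n_de)
  tibble(feature_id = de, lfc = signed_lfc(n_de, config))
}

# Plant the per-compartment differential truth and TF activity.
plant_truth <- function(config, universe) {
  with_seed(derive_seed(config$seed, "plant"), {
    truth <- lapply(config$compartments, function(comp) {
      genes_de <- plant_layer(universe$genes, config)
      # active TFs: planted DE themselves with |lfc| >= 1 so downstream
      # stages see them
      active <- sample(universe$tf_genes, config$n_active_tfs)
      tf_lfc <- runif(config$n_active_tfs, 1, config$effect_range[2]) *
        sample(c(-1, 1), config$n_active_tfs, replace = TRUE)
      genes_de <- genes_de |>
        filter(.data$feature_id %nin% active) |>
        bind_rows(tibble(feature_id = active, lfc = tf_lfc))
      # proteins: coupled to their gene's change, plus independent extras
      gp <- universe$gene_protein_map |>
        inner_join(genes_de, by = c(gene_id = "feature_id"))
      dir <- ifelse(gp$lfc > 0, "increased", "decreased")
      keep <- runif(nrow(gp)) < config$coupling[dir]
      coupled <- tibble(feature_id = gp$protein_id[keep],
                        lfc = gp$lfc[keep] *
                          runif(sum(keep), 0.8, 1.2))
      rest <- setdiff(universe$proteins, coupled$feature_id)
      extra_n <- round(length(universe$proteins) * config$de_fraction / 2)
      extra <- sample(rest, min(extra_n, length(rest)))
      proteins_de <- bind_rows(coupled,
                               tibble(feature_id = extra,
                                      lfc = signed_lfc(length(extra), config)))
      list(
        transcript = genes_de,
        protein = proteins_de,
        metabolite = plant_layer(universe$metabolites, config),
        lipid = plant_layer(universe$lipids, config),
        phospho = plant_layer(universe$phospho_molecules, config),
        active_tfs = tibble(
          tf_gene_id = active,
          direction = ifelse(tf_lfc > 0, "increased", "decreased"))
      )
    })
    names(truth) <- config$compartments
    # blood: metabolite-only, fold changes correlated with the first organ
    # cor(r*X + e, X) = r exactly when sd(e) = sd(X) * sqrt(1 - r^2)
    organ <- truth[[1]]$metabolite
    r <- config$blood_cor
    s <- if (nrow(organ) > 1) sd(organ$lfc) else 1
    blood_lfc <- r * organ$lfc + rnorm(nrow(organ), sd = s * sqrt(1 - r^2))
    blood <- tibble(feature_id = organ$feature_id, lfc = blood_lfc) |>
      filter(abs(.data$lfc) >= 0.5)
    truth$blood <- list(metabolite = blood)
    truth
  })
}

#' Generate a random knowledge base with planted TF enrichment
#'
#' Random enzyme-to-reaction assignments (each enzyme catalyses 1-3
#' reactions), disjoint random substrate/product sets, random allosteric
#' entries, pathways partitioning the reactions, a kinase-TF table whose
#' first entry is an inactivating-phosphorylation TF (Foxo1-like), and
#' motif target sets in which planted active TFs are enriched for planted
#' DEGs of their own direction at odds ratio `tf_target_or`.
#'
#' @param config a `sim_config`.
#' @param universe internal ID universe (defaults regenerated from
#'   `config`).
#' @param truth planted truth from the study generator; `NULL` plants a
#'   fresh one.
#' @return a `knowledge_base`.
#' @export
generate_knowledge_base <- function(config, universe = make_universe(config),
                                    truth = NULL) {
  if (is.null(truth)) truth <- plant_truth(config, universe)
  with_seed(derive_seed(config$seed, "kb"), {
    rx_ids <- sprintf("R%03d", seq_len(config$n_reactions))
    # enzyme -> 1..3 reactions, then guarantee every reaction an enzyme
    assign <- lapply(universe$enzymes, function(e)
      sample(rx_ids, sample(1:3, 1)))
    names(assign) <- universe$enzymes
    long <- tibble(enzyme_id = rep(names(assign), lengths(assign)),
                   reaction_id = unlist(assign))
    empty <- setdiff(rx_ids, long$reaction_id)
    if (length(empty) > 0) {
      long <- bind_rows(long, tibble(
        enzyme_id = sample(universe$enzymes, length(empty), replace = TRUE),
        reaction_id = empty))
    }
    enzymes_by_rx <- split(long$enzyme_id, long$reaction_id)[rx_ids]
    subs <- lapply(rx_ids, function(r)
      sample(universe$metabolites, sample(1:2, 1)))
    prods <- lapply(seq_along(rx_ids), function(i)
      sample(setdiff(universe$metabolites, subs[[i]]), sample(1:2, 1)))
    # pathways partition the reactions
    pclasses <- rep_len(c("carbohydrate", "amino_acid", "lipid", "nucleotide",
                          "other"), config$n_pathways)
    membership <- sample(rep_len(seq_len(config$n_pathways),
                                 config$n_reactions))
    pathways <- tibble(
      pathway_id = sprintf("path%02d", seq_len(config$n_pathways)),
      class = pclasses,
      reaction_ids = lapply(seq_len(config$n_pathways),
                            function(i) rx_ids[membership == i]))
    reactions <- tibble(
      reaction_id = rx_ids,
      enzyme_ids = lapply(enzymes_by_rx, unique),
      substrate_ids = subs,
      product_ids = prods,
      reversible = runif(config$n_reactions) < 0.3,
      pathway_ids = lapply(membership, function(i) pathways$pathway_id[i]))
    allosteric <- tibble(
      metabolite_id = sample(universe$metabolites, 2 * config$n_reactions,
                             replace = TRUE),
      enzyme_protein_id = sample(universe$enzymes, 2 * config$n_reactions,
                                 replace = TRUE),
      mode = sample(c("activator", "inhibitor"), 2 * config$n_reactions,
                    replace = TRUE)) |>
      distinct()
    # motif targets: planted enrichment for active TFs
    p0 <- config$tf_target_base_p
    odds1 <- config$tf_target_or * p0 / (1 - p0)
    p1 <- odds1 / (1 + odds1)
    active_dir <- bind_rows(lapply(config$compartments, function(comp)
      truth[[comp]]$active_tfs |> mutate(compartment = comp))) |>
      distinct(.data$tf_gene_id, .keep_all = TRUE)
    de_sets <- lapply(config$compartments, function(comp) {
      g <- truth[[comp]]$transcript
      list(increased = g$feature_id[g$lfc > 0],
           decreased = g$feature_id[g$lfc < 0])
    })
    names(de_sets) <- config$compartments
    motifs <- bind_rows(lapply(universe$tf_genes, function(tf) {
      row <- active_dir |> filter(.data$tf_gene_id == tf)
      cand <- setdiff(universe$genes, tf)
      if (nrow(row) == 1) {
        hot <- intersect(cand,
                         de_sets[[row$compartment]][[row$direction]])
        p <- ifelse(cand %in% hot, p1, p0)
      } else {
        p <- rep(p0, length(cand))
      }
      targets <- cand[runif(length(cand)) < p]
      if (length(targets) == 0) targets <- sample(cand, 3)
      tibble(tf_gene_id = tf, motif_id = paste0("M_", tf),
             target_ids = list(targets))
    }))
    kinases <- setdiff(universe$phospho_molecules, universe$tf_genes)
    kinase_tf <- bind_rows(
      tibble(kinase_id = kinases[1], tf_id = universe$tf_genes[1],
             phospho_effect = "inactivating"),
      tibble(kinase_id = sample(kinases, min(4, length(kinases))),
             tf_id = sample(universe$tf_genes[-1],
                            min(4, length(kinases))),
             phospho_effect = "activating"))
    metabolite_class <- tibble(
      metabolite_id = universe$metabolites,
      class = sample(c("carbohydrate", "amino_acid", "lipid", "nucleotide",
                       "peptide", "cofactor"),
                     config$n_metabolites, replace = TRUE))
    suppressWarnings(knowledge_base(reactions, allosteric, motifs, kinase_tf,
                                    universe$gene_protein_map,
                                    metabolite_class, pathways))
  })
}

#' Simulate an RNA-seq count table
#'
#' Negative-binomial counts (variance \eqn{\mu + \phi\mu^2}) around
#' log-normal gene baselines with per-sample library-size factors drawn
#' uniformly within +/-30%; planted features get a condition-specific mean
#' shift of their planted log2 fold change.
#'
#' @param config a `sim_config`.
#' @param design sample design for the transcript layer.
#' @param compartment compartment label.
#' @param truth planted tibble (`feature_id`, `lfc`); `NULL` plants one
#'   from `config$de_fraction` (returned in the `planted` attribute).
#' @return a transcript `omics_table` with attribute `planted`.
#' @export
simulate_counts <- function(config, design, compartment = "liver",
                            truth = NULL) {
  universe <- make_universe(config)
  with_seed(derive_seed(config$seed, paste0("counts_", compartment)), {
    if (is.null(truth)) truth <- plant_layer(universe$genes, config)
    lfc <- setNames(rep(0, config$n_genes), universe$genes)
    lfc[truth$feature_id] <- truth$lfc
    base <- rlnorm(config$n_genes, meanlog = log(150), sdlog = 1.2)
    libf <- runif(nrow(design), 0.7, 1.3)
    is_case <- design$condition == "case"
    mu <- outer(base, libf) * 2^outer(lfc, as.numeric(is_case))
    counts <- matrix(rnbinom(length(mu), mu = mu,
                             size = 1 / config$nb_dispersion),
                     nrow = config$n_genes,
                     dimnames = list(universe$genes, design$sample_id))
    out <- omics_table(
      tibble(feature_id = universe$genes) |>
        bind_cols(as_tibble(counts)),
      layer = "transcript", compartment = compartment)
    attr(out, "planted") <- truth
    out
  })
}

#' Simulate a log-normal abundance table
#'
#' Protein, metabolite or lipid abundances drawn log-normally with the
#' configured coefficient of variation; planted features are shifted
#' multiplicatively by their planted fold change in the case group.
#'
#' @inheritParams simulate_counts
#' @param layer `"protein"`, `"metabolite"` or `"lipid"`.
#' @return an `omics_table` with attribute `planted`.
#' @export
simulate_abundances <- function(config, design,
                                layer = c("protein", "metabolite", "lipid"),
                                compartment = "liver", truth = NULL) {
  layer <- match.arg(layer)
  universe <- make_universe(config)
  ids <- switch(layer, protein = universe$proteins,
                metabolite = universe$metabolites, lipid = universe$lipids)
  with_seed(derive_seed(config$seed,
                        paste0("abund_", layer, "_", compartment)), {
    if (is.null(truth)) truth <- plant_layer(ids, config)
    lfc <- setNames(rep(0, length(ids)), ids)
    lfc[truth$feature_id] <- truth$lfc
    sdlog <- sqrt(log(1 + config$abundance_cv^2))
    base <- rlnorm(length(ids), meanlog = log(1e4), sdlog = 1)
    is_case <- design$condition == "case"
    meanlog <- log(base) + log(2) * outer(lfc, as.numeric(is_case))
    vals <- matrix(rlnorm(length(meanlog), meanlog = meanlog, sdlog = sdlog),
                   nrow = length(ids),
                   dimnames = list(ids, design$sample_id))
    out <- omics_table(
      tibble(feature_id = ids) |> bind_cols(as_tibble(vals)),
      layer = layer, compartment = compartment)
    attr(out, "planted") <- truth
    out
  })
}

#' Simulate phospho/total western-blot pairs
#'
#' Generates a (phospho, total) abundance pair per signalling molecule;
#' planted differentially phosphorylated molecules change only the
#' phospho/total ratio, never the total.
#'
#' @inheritParams simulate_counts
#' @return a `phospho_pair` `omics_table` (phospho rows keyed by the
#'   molecule ID, totals by `<id>_total`) with attribute `planted`.
#' @export
simulate_phospho_pairs <- function(config, design, compartment = "liver",
                                   truth = NULL) {
  universe <- make_universe(config)
  mols <- universe$phospho_molecules
  with_seed(derive_seed(config$seed, paste0("phospho_", compartment)), {
    if (is.null(truth)) truth <- plant_layer(mols, config)
    lfc <- setNames(rep(0, length(mols)), mols)
    lfc[truth$feature_id] <- truth$lfc
    sdlog <- sqrt(log(1 + config$phospho_cv^2))
    total_base <- rlnorm(length(mols), log(1e3), 0.5)
    ratio_base <- runif(length(mols), 0.2, 0.8)
    is_case <- design$condition == "case"
    total <- matrix(rlnorm(length(mols) * nrow(design),
                           meanlog = rep(log(total_base), nrow(design)),
                           sdlog = sdlog),
                    nrow = length(mols),
                    dimnames = list(paste0(mols, "_total"),
                                    design$sample_id))
    ratio_meanlog <- log(ratio_base) +
      log(2) * outer(lfc, as.numeric(is_case))
    ratio <- matrix(rlnorm(length(ratio_meanlog), meanlog = ratio_meanlog,
                           sdlog = sdlog),
                    nrow = length(mols))
    phospho <- total * ratio
    rownames(phospho) <- mols
    vals <- rbind(phospho, total)
    out <- omics_table(
      tibble(feature_id = rownames(vals)) |> bind_cols(as_tibble(vals)),
      layer = "phospho_pair", compartment = compartment,
      pairs = tibble(phospho_id = mols, total_id = paste0(mols, "_total")))
    attr(out, "planted") <- truth
    out
  })
}

#' Generate a complete synthetic study with planted ground truth
#'
#' Produces a self-consistent bundle: omic tables for every organ
#' compartment (transcripts, proteins, metabolites, lipids, phospho pairs)
#' plus blood metabolites whose fold changes correlate with the first
#' organ's at the configured Pearson target; a random knowledge base with
#' planted TF-target enrichment; and a `ground_truth` element holding the
#' planted differential sets, planted effect sizes, active TFs, and the
#' expected trans-omic network per organ computed at generation time by
#' the independent brute-force oracle ([enumerate_expected_network()]),
#' which shares no code with the pipeline's network builder.
#'
#' @param config a `sim_config`.
#' @param simulate_tables set `FALSE` to generate only IDs, knowledge base
#'   and ground truth (fast path for network-logic checks).
#' @return list with `tables` (per compartment, per layer), `designs` (per
#'   layer), `kb`, and `ground_truth`.
#' @export
generate_study <- function(config, simulate_tables = TRUE) {
  universe <- make_universe(config)
  truth <- plant_truth(config, universe)
  kb <- generate_knowledge_base(config, universe, truth)
  expected <- lapply(config$compartments, function(comp)
    enumerate_expected_network(truth[[comp]], kb, comp))
  names(expected) <- config$compartments
  designs <- list(
    transcript = make_design(config$replicates$transcript[1],
                             config$replicates$transcript[2], "tr"),
    protein = make_design(config$replicates$protein[1],
                          config$replicates$protein[2], "pro"),
    metabolite = make_design(config$replicates$metabolite[1],
                             config$replicates$metabolite[2], "met"),
    lipid = make_design(config$replicates$lipid[1],
                        config$replicates$lipid[2], "lip"),
    phospho = make_design(config$replicates$phospho[1],
                          config$replicates$phospho[2], "ph"))
  tables <- NULL
  if (simulate_tables) {
    tables <- lapply(config$compartments, function(comp) list(
      transcript = simulate_counts(config, designs$transcript, comp,
                                   truth[[comp]]$transcript),
      protein = simulate_abundances(config, designs$protein, "protein",
                                    comp, truth[[comp]]$protein),
      metabolite = simulate_abundances(config, designs$metabolite,
                                       "metabolite", comp,
                                       truth[[comp]]$metabolite),
      lipid = simulate_abundances(config, designs$lipid, "lipid", comp,
                                  truth[[comp]]$lipid),
      phospho = simulate_phospho_pairs(config, designs$phospho, comp,
                                       truth[[comp]]$phospho)))
    names(tables) <- config$compartments
    tables$blood <- list(
      metabolite = simulate_abundances(config, designs$metabolite,
                                       "metabolite", "blood",
                                       truth$blood$metabolite))
  }
  list(config = config, tables = tables, designs = designs, kb = kb,
       ground_truth = list(planted = truth, expected_networks = expected))
}
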