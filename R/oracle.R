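#' Brute-force enumeration of the expected trans-omic network
#'
#' Independent oracle used by the synthetic-study generator: given the
#' planted truth of one compartment (which molecules changed and in which
#' direction, plus the planted active TFs) and a knowledge base, it
#' enumerates the expected network by looping over every reaction, enzyme,
#' allosteric entry, gene-protein pair, motif target and kinase-TF pair,
#' applying the sign rules with explicit lookup tables. It deliberately
#' shares no code with [build_network()] or the edge constructors, so exact
#' agreement between the two is a meaningful check of the pipeline.
#'
#' @param truth_comp planted truth for one compartment: list with tibbles
#'   `transcript`, `protein`, `metabolite`, `phospho` (columns
#'   `feature_id`, `lfc`) and `active_tfs` (`tf_gene_id`, `direction`).
#' @param kb a `knowledge_base`.
#' @param compartment compartment label.
#' @param mass_action_signed include signed substrate/product edges?
#' @param fold_mixed fold within-layer conflicts into `controversial`?
#' @return a `transomic_network`-shaped list (nodes, edges,
#'   reaction_class), comparable with [build_network()] output.
#' @export
enumerate_expected_network <- function(truth_comp, kb, compartment,
                                       mass_action_signed = FALSE,
                                       fold_mixed = FALSE) {
  dir_of <- function(tbl) {
    d <- ifelse(tbl$lfc > 0, "increased", "decreased")
    setNames(d, tbl$feature_id)
  }
  gene_dir <- dir_of(truth_comp$transcript)
  prot_dir <- dir_of(truth_comp$protein)
  met_dir <- dir_of(truth_comp$metabolite)
  pp_dir <- if (!is.null(truth_comp$phospho)) dir_of(truth_comp$phospho)
            else character()
  tf_dir <- setNames(truth_comp$active_tfs$direction,
                     truth_comp$active_tfs$tf_gene_id)

  # explicit 2x2 sign table
  sign_table <- matrix(c("activating", "inhibiting",
                         "inhibiting", "activating"),
                       nrow = 2,
                       dimnames = list(c("increased", "decreased"),
                                       c("activation", "inhibition")))

  edges <- list()
  add_edge <- function(src, slayer, tgt, tlayer, type, mode, sign) {
    edges[[length(edges) + 1]] <<-
      c(src, slayer, tgt, tlayer, type, mode, sign)
  }

  # bottom layer: enzyme and metabolite regulation of reactions
  for (i in seq_len(nrow(kb$reactions))) {
    r <- kb$reactions$reaction_id[i]
    for (e in kb$reactions$enzyme_ids[[i]]) {
      if (e %in% names(prot_dir)) {
        add_edge(e, "enzyme_protein", r, "reaction", "enzyme_reaction",
                 "activation", sign_table[prot_dir[[e]], "activation"])
      }
    }
    for (j in seq_len(nrow(kb$allosteric))) {
      met <- kb$allosteric$metabolite_id[j]
      enz <- kb$allosteric$enzyme_protein_id[j]
      if (!met %in% names(met_dir)) next
      if (!enz %in% kb$reactions$enzyme_ids[[i]]) next
      mode <- if (kb$allosteric$mode[j] == "activator") "activation"
              else "inhibition"
      add_edge(met, "metabolite", r, "reaction", "allosteric", mode,
               sign_table[met_dir[[met]], mode])
    }
    if (mass_action_signed) {
      for (met in kb$reactions$substrate_ids[[i]]) {
        if (met %in% names(met_dir)) {
          add_edge(met, "metabolite", r, "reaction", "mass_action",
                   "substrate", sign_table[met_dir[[met]], "activation"])
        }
      }
      for (met in kb$reactions$product_ids[[i]]) {
        if (met %in% names(met_dir)) {
          add_edge(met, "metabolite", r, "reaction", "mass_action",
                   "product", sign_table[met_dir[[met]], "inhibition"])
        }
      }
    }
  }
  em <- do.call(rbind, edges)
  kept_rx <- if (is.null(em)) character() else unique(em[, 3])

  # gene -> protein, for concordant pairs whose protein regulates a kept
  # reaction
  kept_prot <- if (is.null(em)) character() else
    unique(em[em[, 2] == "enzyme_protein", 1])
  kept_genes <- character()
  for (i in seq_len(nrow(kb$gene_protein_map))) {
    g <- kb$gene_protein_map$gene_id[i]
    p <- kb$gene_protein_map$protein_id[i]
    if (g %in% names(gene_dir) && p %in% names(prot_dir) &&
        gene_dir[[g]] == prot_dir[[p]] && p %in% kept_prot) {
      add_edge(g, "enzyme_mrna", p, "enzyme_protein", "gene_protein",
               "activation", sign_table[gene_dir[[g]], "activation"])
      kept_genes <- c(kept_genes, g)
    }
  }
  kept_genes <- unique(kept_genes)

  # TF -> gene for active TFs, consistent direction, gene kept
  kept_tfs <- character()
  for (i in seq_len(nrow(kb$motifs))) {
    tf <- kb$motifs$tf_gene_id[i]
    if (!tf %in% names(tf_dir)) next
    for (g in kb$motifs$target_ids[[i]]) {
      if (g %in% kept_genes && g %in% names(gene_dir) &&
          gene_dir[[g]] == tf_dir[[tf]]) {
        add_edge(tf, "tf", g, "enzyme_mrna", "tf_gene", "activation",
                 sign_table[gene_dir[[g]], "activation"])
        kept_tfs <- c(kept_tfs, tf)
      }
    }
  }
  kept_tfs <- unique(kept_tfs)

  # kinase -> TF for differentially phosphorylated kinases
  for (i in seq_len(nrow(kb$kinase_tf))) {
    k <- kb$kinase_tf$kinase_id[i]
    t <- kb$kinase_tf$tf_id[i]
    if (k %in% names(pp_dir) && t %in% kept_tfs) {
      add_edge(k, "insulin_signal", t, "tf", "kinase_tf", "activation",
               sign_table[pp_dir[[k]], "activation"])
    }
  }

  em <- do.call(rbind, edges)
  edge_tbl <- if (is.null(em)) empty_edges() else {
    tibble(source = em[, 1], source_layer = em[, 2], target = em[, 3],
           target_layer = em[, 4], type = em[, 5], mode = em[, 6],
           sign = em[, 7]) |> distinct()
  }
  edge_tbl <- edge_tbl[order(edge_tbl$type, edge_tbl$source,
                             edge_tbl$target), ]

  all_dir <- c(setNames(unname(gene_dir), node_key("enzyme_mrna",
                                                   names(gene_dir))),
               setNames(unname(prot_dir), node_key("enzyme_protein",
                                                   names(prot_dir))),
               setNames(unname(met_dir), node_key("metabolite",
                                                  names(met_dir))),
               setNames(unname(pp_dir), node_key("insulin_signal",
                                                 names(pp_dir))),
               setNames(unname(tf_dir), node_key("tf", names(tf_dir))))
  node_rows <- unique(rbind(
    cbind(edge_tbl$source, edge_tbl$source_layer),
    cbind(edge_tbl$target, edge_tbl$target_layer)))
  nodes <- if (is.null(node_rows) || nrow(node_rows) == 0) {
    tibble(id = character(), layer = character(), change = character())
  } else {
    tibble(id = node_rows[, 1], layer = node_rows[, 2]) |>
      mutate(change = ifelse(.data$layer == "reaction", NA_character_,
                             unname(all_dir[node_key(.data$layer,
                                                     .data$id)])))
  }
  nodes <- nodes[order(nodes$layer, nodes$id), ]

  # classification by counting signs per layer
  rx_ids <- sort(unique(nodes$id[nodes$layer == "reaction"]))
  cls <- character(length(rx_ids))
  for (i in seq_along(rx_ids)) {
    r <- rx_ids[i]
    here <- edge_tbl[edge_tbl$target == r &
                       edge_tbl$target_layer == "reaction", ]
    e_act <- sum(here$source_layer == "enzyme_protein" &
                   here$sign == "activating")
    e_inh <- sum(here$source_layer == "enzyme_protein" &
                   here$sign == "inhibiting")
    m_act <- sum(here$source_layer == "metabolite" &
                   here$sign == "activating")
    m_inh <- sum(here$source_layer == "metabolite" &
                   here$sign == "inhibiting")
    if (e_act + e_inh + m_act + m_inh == 0) {
      cls[i] <- "unclassified"
    } else if ((e_act > 0 && e_inh > 0) || (m_act > 0 && m_inh > 0)) {
      cls[i] <- if (fold_mixed) "controversial" else "mixed_within_layer"
    } else if (e_inh == 0 && m_inh == 0) {
      cls[i] <- "activated"
    } else if (e_act == 0 && m_act == 0) {
      cls[i] <- "inhibited"
    } else {
      cls[i] <- "controversial"
    }
  }

  structure(list(compartment = compartment,
                 nodes = as_tibble(nodes),
                 edges = as_tibble(edge_tbl),
                 reaction_class = tibble(reaction_id = rx_ids, class = cls),
                 mass_action_signed = mass_action_signed,
                 fold_mixed = fold_mixed),
            class = "transomic_network")
}
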