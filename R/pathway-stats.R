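#' Overlap percentage, rounded as printed
#'
#' `round(100 * n_overlap / n_total)` with half-away-from-zero rounding,
#' the convention used for printed overlap summaries such as the share of
#' differential proteins encoded by differential genes.
#'
#' @param n_overlap overlap count.
#' @param n_total total count (> 0).
#' @return integer percentage.
#' @export
overlap_summary <- function(n_overlap, n_total) {
  assert_that(n_total > 0, "n_total must be positive")
  assert_that(n_overlap >= 0 && n_overlap <= n_total,
              "need 0 <= n_overlap <= n_total")
  as.integer(round_half_up(100 * n_overlap / n_total))
}

#' Fraction of controversial reactions
#'
#' @param n_controversial count of reactions with opposing Enzyme Protein
#'   vs Metabolite layer input, or a `transomic_network` (then `n_total` is
#'   ignored).
#' @param n_total total differentially regulated reactions.
#' @return list with `n_controversial`, `n_total` and `percent`
#'   (unrounded).
#' @export
controversial_fraction <- function(n_controversial, n_total = NULL) {
  if (inherits(n_controversial, "transomic_network")) {
    rc <- n_controversial$reaction_class
    assert_that(nrow(rc) > 0, "network has no classified reactions")
    n_total <- nrow(rc)
    n_controversial <- sum(rc$class == "controversial")
  }
  assert_that(n_total > 0, "n_total must be positive")
  list(n_controversial = n_controversial, n_total = n_total,
       percent = 100 * n_controversial / n_total)
}

#' Per-pathway regulation percentages
#'
#' For each pathway with at least one differentially regulated reaction in
#' the network: the percentage of its (in-network) reactions receiving at
#' least one activating / inhibiting edge from the Metabolite layer and from
#' the Enzyme Protein layer. A reaction with edges of both signs counts
#' toward both numerators. Pathways with zero in-network reactions are
#' excluded and listed in the `excluded` attribute.
#'
#' @param net a `transomic_network`.
#' @param kb the `knowledge_base` it was built from.
#' @return tibble with `pathway_id`, `class`, `n_diffreg_reactions` and the
#'   four percentage columns.
#' @export
pathway_regulation_percentages <- function(net, kb) {
  rx_in_net <- net$reaction_class$reaction_id
  metab_types <- c("allosteric", if (isTRUE(net$mass_action_signed))
    "mass_action")
  rx_edges <- net$edges |> filter(.data$target_layer == "reaction")
  pct <- function(rx, layer, sgn) {
    hits <- rx_edges |>
      filter(.data$source_layer == layer, .data$sign == sgn,
             .data$target %in% rx,
             layer != "metabolite" | .data$type %in% metab_types)
    100 * length(unique(hits$target)) / length(rx)
  }
  rows <- pmap(kb$pathways[c("pathway_id", "class", "reaction_ids")],
               function(pathway_id, class, reaction_ids) {
    rx <- intersect(reaction_ids, rx_in_net)
    if (length(rx) == 0) return(NULL)
    tibble(pathway_id = pathway_id, class = class,
           n_diffreg_reactions = length(rx),
           pct_activated_by_metabolite = pct(rx, "metabolite", "activating"),
           pct_inhibited_by_metabolite = pct(rx, "metabolite", "inhibiting"),
           pct_activated_by_enzyme = pct(rx, "enzyme_protein", "activating"),
           pct_inhibited_by_enzyme = pct(rx, "enzyme_protein", "inhibiting"))
  })
  out <- bind_rows(rows)
  attr(out, "excluded") <- setdiff(kb$pathways$pathway_id, out$pathway_id)
  out
}

# reactions reachable from each DRTF via tf -> gene -> protein -> reaction
# chains of in-network edges
drtf_reactions <- function(net) {
  e <- net$edges
  tf_gene <- e |> filter(.data$type == "tf_gene") |>
    select(tf = "source", gene = "target")
  gp <- e |> filter(.data$type == "gene_protein") |>
    select(gene = "source", protein = "target")
  er <- e |> filter(.data$type == "enzyme_reaction") |>
    select(protein = "source", reaction = "target")
  tf_gene |>
    inner_join(gp, by = "gene", relationship = "many-to-many") |>
    inner_join(er, by = "protein", relationship = "many-to-many") |>
    distinct(.data$tf, .data$reaction)
}

#' DRTF-pathway association by one-tailed Fisher's exact test
#'
#' For each DRTF, the set of reactions it regulates through a TF -> gene ->
#' protein -> reaction chain of differential regulations is tested for
#' enrichment in each pathway: a 2x2 table over the universe of all
#' differentially regulated reactions in the network, one-tailed
#' (enrichment) Fisher p, Benjamini-Hochberg q across all tested
#' (DRTF, pathway) pairs, significant iff q < `alpha`. DRTFs regulating no
#' reaction are excluded.
#'
#' @param net a `transomic_network`.
#' @param kb the `knowledge_base`.
#' @param alpha significance threshold on q (default 0.01).
#' @return tibble with `tf_gene_id`, `pathway_id`, `count` (overlap), `p`,
#'   `q`, `significant`.
#' @export
drtf_pathway_enrichment <- function(net, kb, alpha = 0.01) {
  universe <- net$reaction_class$reaction_id
  reach <- drtf_reactions(net)
  if (nrow(reach) == 0) {
    return(tibble(tf_gene_id = character(), pathway_id = character(),
                  count = integer(), p = numeric(), q = numeric(),
                  significant = logical()))
  }
  per_tf <- split(reach$reaction, reach$tf)
  rows <- purrr::imap(per_tf, function(rx, tf) {
    bind_rows(pmap(kb$pathways[c("pathway_id", "reaction_ids")],
                   function(pathway_id, reaction_ids) {
      path_rx <- intersect(reaction_ids, universe)
      if (length(path_rx) == 0) return(NULL)
      k <- length(intersect(rx, path_rx))
      tibble(tf_gene_id = tf, pathway_id = pathway_id, count = k,
             p = phyper(k - 1, length(path_rx),
                        length(universe) - length(path_rx),
                        length(rx), lower.tail = FALSE))
    }))
  })
  out <- bind_rows(rows)
  out$q <- bh_qvalues(out$p)
  out$significant <- out$q < alpha
  arrange(out, .data$q, .data$tf_gene_id, .data$pathway_id)
}

#' DEM tallies by metabolite class
#'
#' Counts differentially expressed metabolites per (compartment, metabolite
#' class, direction); metabolites missing from the class map are binned as
#' `"unclassified"`.
#'
#' @param dems_by_compartment named list of metabolite-layer diff-result
#'   tibbles, one per compartment.
#' @param metabolite_class tibble with `metabolite_id`, `class`.
#' @return tibble with `compartment`, `class`, `direction`, `n`.
#' @export
dem_class_summary <- function(dems_by_compartment, metabolite_class) {
  rows <- imap(dems_by_compartment, function(d, comp) {
    d |>
      filter(.data$class != "unchanged") |>
      left_join(metabolite_class |>
                  rename(metabolite_class = "class"),
                by = c(feature_id = "metabolite_id")) |>
      mutate(compartment = comp,
             metabolite_class = tidyr::replace_na(.data$metabolite_class,
                                                  "unclassified"))
  })
  bind_rows(rows) |>
    mutate(direction = .data$class, class = .data$metabolite_class) |>
    count(.data$compartment, .data$class, .data$direction, name = "n")
}
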