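#' Combine a change direction with a regulation mode into an edge sign
#'
#' The sign algebra of differential regulation: a regulation is `activating`
#' in the case condition iff (increased, activation) or (decreased,
#' inhibition); the other two cells of the 2x2 table give `inhibiting`.
#' Vectorised and total on its domain.
#'
#' @param change `"increased"` or `"decreased"`.
#' @param mode `"activation"` or `"inhibition"`.
#' @return `"activating"` or `"inhibiting"`.
#' @export
combine_signs <- function(change, mode) {
  if (length(change) == 0) return(character(0))
  assert_that(all(change %in% c("increased", "decreased")),
              "change must be increased/decreased")
  assert_that(all(mode %in% c("activation", "inhibition")),
              "mode must be activation/inhibition")
  ifelse((change == "increased") == (mode == "activation"),
         "activating", "inhibiting")
}

edge_tibble <- function(source, source_layer, target, target_layer,
                        type, mode, sign) {
  tibble(source = source, source_layer = source_layer,
         target = target, target_layer = target_layer,
         type = type, mode = mode, sign = sign)
}

empty_edges <- function() {
  edge_tibble(character(), character(), character(), character(),
              character(), character(), character())
}

#' Gene-to-protein differential regulations
#'
#' One edge per gene-protein map pair in which the DEG and the DEP changed
#' in the same direction (activating if both increased, inhibiting if both
#' decreased). Discordant pairs produce no edge and are returned in the
#' `discordant` attribute; a gene mapped to several proteins yields one edge
#' per concordant protein.
#'
#' @param degs transcript-layer diff results.
#' @param deps protein-layer diff results.
#' @param gene_protein_map tibble with `gene_id`, `protein_id`.
#' @return edge tibble (source layer `enzyme_mrna`, target layer
#'   `enzyme_protein`) with a `discordant` tibble attribute.
#' @export
gene_protein_edges <- function(degs, deps, gene_protein_map) {
  pairs <- gene_protein_map |>
    inner_join(degs |> filter(.data$class != "unchanged") |>
                 select("feature_id", gene_class = "class"),
               by = c(gene_id = "feature_id")) |>
    inner_join(deps |> filter(.data$class != "unchanged") |>
                 select("feature_id", protein_class = "class"),
               by = c(protein_id = "feature_id"))
  concordant <- pairs |> filter(.data$gene_class == .data$protein_class)
  out <- edge_tibble(
    source = concordant$gene_id, source_layer = "enzyme_mrna",
    target = concordant$protein_id, target_layer = "enzyme_protein",
    type = "gene_protein", mode = "activation",
    sign = if (nrow(concordant)) combine_signs(concordant$gene_class,
                                               "activation") else character())
  attr(out, "discordant") <-
    pairs |> filter(.data$gene_class != .data$protein_class)
  out
}

#' Enzyme-to-reaction differential regulations
#'
#' Differentially expressed metabolic enzymes (DEMEs) are the DEPs that
#' appear as enzymes in the reaction map; each DEME regulates every reaction
#' it catalyses, activating if the enzyme increased, inhibiting if it
#' decreased (mode `activation`).
#'
#' @param deps protein-layer diff results.
#' @param kb a `knowledge_base`.
#' @return edge tibble (source layer `enzyme_protein`, target layer
#'   `reaction`).
#' @export
enzyme_reaction_edges <- function(deps, kb) {
  demes <- deps |> filter(.data$class != "unchanged")
  hits <- reaction_enzyme_long(kb) |>
    inner_join(demes |> select("feature_id", "class"),
               by = c(enzyme_id = "feature_id"))
  if (nrow(hits) == 0) return(empty_edges())
  edge_tibble(
    source = hits$enzyme_id, source_layer = "enzyme_protein",
    target = hits$reaction_id, target_layer = "reaction",
    type = "enzyme_reaction", mode = "activation",
    sign = combine_signs(hits$class, "activation")) |>
    distinct()
}

#' Allosteric differential regulations
#'
#' For each allosteric table entry whose metabolite is a DEM, one edge per
#' reaction of the regulated enzyme. The sign combines the DEM's change with
#' the regulator mode (activator -> activation, inhibitor -> inhibition):
#' e.g. an increased DEM annotated as inhibitor gives an inhibiting edge.
#' Entries whose enzyme is absent from the reaction map are skipped with a
#' warning.
#'
#' @param dems metabolite-layer diff results.
#' @param kb a `knowledge_base`.
#' @return edge tibble (source layer `metabolite`, target layer `reaction`).
#' @export
allosteric_edges <- function(dems, kb) {
  diff <- dems |> filter(.data$class != "unchanged")
  entries <- kb$allosteric |>
    inner_join(diff |> select("feature_id", "class"),
               by = c(metabolite_id = "feature_id"))
  known <- unique(reaction_enzyme_long(kb)$enzyme_id)
  orphan <- setdiff(unique(entries$enzyme_protein_id), known)
  if (length(orphan) > 0) {
    warn(paste0("allosteric entries with unknown enzyme skipped: ",
                paste(orphan, collapse = ", ")))
  }
  hits <- entries |>
    inner_join(reaction_enzyme_long(kb),
               by = c(enzyme_protein_id = "enzyme_id"),
               relationship = "many-to-many")
  if (nrow(hits) == 0) return(empty_edges())
  edge_tibble(
    source = hits$metabolite_id, source_layer = "metabolite",
    target = hits$reaction_id, target_layer = "reaction",
    type = "allosteric",
    mode = ifelse(hits$mode == "activator", "activation", "inhibition"),
    sign = combine_signs(hits$class,
                         ifelse(hits$mode == "activator",
                                "activation", "inhibition"))) |>
    distinct()
}

#' Substrate/product (mass-action) differential regulations
#'
#' Substrate DEMs act with mode `substrate` (activation-like: increased ->
#' activating); product DEMs with mode `product` (inhibition-like:
#' increased -> inhibiting). Under `treat_reversible = "both_sides"`,
#' products of reversible reactions are treated as substrates of the reverse
#' direction and take the substrate rule instead.
#'
#' @param dems metabolite-layer diff results.
#' @param kb a `knowledge_base`.
#' @param treat_reversible `"substrates_only"` (default) or `"both_sides"`.
#' @return edge tibble (source layer `metabolite`, target layer `reaction`).
#' @export
mass_action_edges <- function(dems, kb,
                              treat_reversible = c("substrates_only",
                                                   "both_sides")) {
  treat_reversible <- match.arg(treat_reversible)
  diff <- dems |> filter(.data$class != "unchanged")
  long <- kb$reactions |>
    select("reaction_id", "reversible", "substrate_ids", "product_ids") |>
    tidyr::pivot_longer(c("substrate_ids", "product_ids"),
                        names_to = "role", values_to = "metabolite_id") |>
    tidyr::unnest(cols = "metabolite_id") |>
    mutate(role = ifelse(.data$role == "substrate_ids",
                         "substrate", "product"))
  hits <- long |>
    inner_join(diff |> select("feature_id", "class"),
               by = c(metabolite_id = "feature_id"))
  if (nrow(hits) == 0) return(empty_edges())
  hits <- hits |>
    mutate(mode_used = ifelse(
      .data$role == "product" & .data$reversible &
        treat_reversible == "both_sides",
      "substrate", .data$role))
  edge_tibble(
    source = hits$metabolite_id, source_layer = "metabolite",
    target = hits$reaction_id, target_layer = "reaction",
    type = "mass_action", mode = hits$mode_used,
    sign = combine_signs(hits$class,
                         ifelse(hits$mode_used == "substrate",
                                "activation", "inhibition"))) |>
    distinct()
}

#' TF-to-gene differential regulations
#'
#' Under the activation-only TF model, a DRTF regulates each DEG in its
#' motif target set whose change direction is consistent with the TF's
#' activity change (increased-activity TF -> increased DEG, decreased ->
#' decreased); the edge sign then equals the DEG's direction. Inconsistent
#' TF-target pairs produce no edge.
#'
#' @param drtfs DRTF tibble.
#' @param degs transcript-layer diff results.
#' @param kb a `knowledge_base` (motif table used).
#' @return edge tibble (source layer `tf`, target layer `enzyme_mrna`).
#' @export
tf_gene_edges <- function(drtfs, degs, kb) {
  if (nrow(drtfs) == 0) return(empty_edges())
  targets <- kb$motifs |>
    select("tf_gene_id", "target_ids") |>
    tidyr::unnest(cols = "target_ids") |>
    rename(target_gene = "target_ids") |>
    distinct()
  hits <- drtfs |>
    distinct(.data$tf_gene_id, .data$activity_change) |>
    inner_join(targets, by = "tf_gene_id", relationship = "many-to-many") |>
    inner_join(degs |> filter(.data$class != "unchanged") |>
                 select("feature_id", "class"),
               by = c(target_gene = "feature_id")) |>
    # activation-only model: consistent iff target moves with the TF's activity
    filter(.data$class == .data$activity_change)
  if (nrow(hits) == 0) return(empty_edges())
  edge_tibble(
    source = hits$tf_gene_id, source_layer = "tf",
    target = hits$target_gene, target_layer = "enzyme_mrna",
    type = "tf_gene", mode = "activation",
    sign = combine_signs(hits$class, "activation")) |>
    distinct()
}

# Re-derive each edge's sign from (source change, mode) and compare; used by
# validation and property tests. `changes` is named by node_key(layer, id).
revalidate_edges <- function(edges, changes) {
  if (nrow(edges) == 0) return(TRUE)
  src <- changes[node_key(edges$source_layer, edges$source)]
  mode <- ifelse(edges$mode %in% c("activation", "substrate"),
                 "activation", "inhibition")
  all(combine_signs(src, mode) == edges$sign)
}
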