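#' Assemble the six-layer trans-omic network for one compartment
#'
#' Integrates the differential molecules and signed differential regulations
#' of one organ into a layered network: Insulin Signal (differentially
#' phosphorylated kinases) -> TF (DRTFs) -> Enzyme mRNA (DEGs) -> Enzyme
#' Protein (DEMEs) -> Metabolic Reaction, with the Metabolite layer feeding
#' the Reaction layer through allosteric (and optionally signed mass-action)
#' regulation. A reaction enters the network iff it receives at least one
#' signed edge from the Enzyme Protein or Metabolite layer; upstream edges
#' (gene-protein, TF-gene, kinase-TF) are kept only when their downstream
#' chain reaches a retained reaction, and nodes are the endpoints of
#' retained edges. Reactions are classified by [classify_reactions()].
#'
#' @param diff_results named list of diff-result tibbles (any of
#'   `transcript`, `protein`, `metabolite`, `phospho_pair`) for one
#'   compartment.
#' @param drtfs DRTF tibble for the compartment (may be empty).
#' @param edges combined regulation-edge tibble (all edge types, one
#'   compartment).
#' @param kb a `knowledge_base`.
#' @param compartment compartment label.
#' @param mass_action_signed do signed mass-action edges take part in
#'   reaction retention and classification (default `FALSE`: allosteric
#'   edges only, mass-action context kept unsigned)?
#' @param fold_mixed fold within-layer conflicts into `controversial`
#'   (default `FALSE`: they get their own class `mixed_within_layer`)?
#' @return a `transomic_network`: list with `compartment`, `nodes`
#'   (`id`, `layer`, `change`), `edges`, and `reaction_class`.
#' @export
build_network <- function(diff_results, drtfs, edges, kb, compartment,
                          mass_action_signed = FALSE, fold_mixed = FALSE) {
  edges <- as_tibble(edges)
  metab_types <- c("allosteric", if (mass_action_signed) "mass_action")
  regulating <- edges |>
    filter(.data$target_layer == "reaction",
           .data$type %in% c("enzyme_reaction", metab_types))
  kept_reactions <- unique(regulating$target)
  # walk upward, keeping edges whose target survives below
  e_rx <- edges |>
    filter(.data$target_layer == "reaction",
           .data$type %in% c("enzyme_reaction", metab_types),
           .data$target %in% kept_reactions)
  kept_proteins <- unique(e_rx$source[e_rx$source_layer == "enzyme_protein"])
  e_gp <- edges |>
    filter(.data$type == "gene_protein", .data$target %in% kept_proteins)
  kept_genes <- unique(e_gp$source)
  e_tf <- edges |>
    filter(.data$type == "tf_gene", .data$target %in% kept_genes)
  kept_tfs <- unique(e_tf$source)
  e_kin <- edges |>
    filter(.data$type == "kinase_tf", .data$target %in% kept_tfs)
  net_edges <- bind_rows(e_kin, e_tf, e_gp, e_rx)

  changes <- node_changes(diff_results, drtfs)
  endpoint <- bind_rows(
    tibble(id = net_edges$source, layer = net_edges$source_layer),
    tibble(id = net_edges$target, layer = net_edges$target_layer)) |>
    distinct()
  missing <- endpoint |>
    filter(.data$layer != "reaction") |>
    filter(node_key(.data$layer, .data$id) %nin% names(changes))
  assert_that(nrow(missing) == 0,
              paste0("edge endpoint(s) with no differential call: ",
                     paste(node_key(missing$layer, missing$id),
                           collapse = ", ")))
  nodes <- endpoint |>
    mutate(change = as.character(
      ifelse(.data$layer == "reaction", NA_character_,
             unname(changes[node_key(.data$layer, .data$id)]))))
  net <- structure(list(compartment = compartment,
                        nodes = arrange(nodes, .data$layer, .data$id),
                        edges = arrange(net_edges, .data$type, .data$source,
                                        .data$target),
                        reaction_class = NULL,
                        mass_action_signed = mass_action_signed,
                        fold_mixed = fold_mixed),
                   class = "transomic_network")
  net$reaction_class <- classify_reactions(net)
  net
}

# map node_key -> change direction, from diff results and DRTF activity
node_changes <- function(diff_results, drtfs) {
  layer_map <- c(transcript = "enzyme_mrna", protein = "enzyme_protein",
                 metabolite = "metabolite", phospho_pair = "insulin_signal")
  rows <- bind_rows(lapply(diff_results, function(d) {
    if (is.null(d) || nrow(d) == 0) return(NULL)
    tibble(layer = layer_map[[d$layer[1]]], id = d$feature_id,
           change = d$class)
  }))
  if (nrow(rows) == 0) {
    rows <- tibble(layer = character(), id = character(),
                   change = character())
  }
  ch <- setNames(rows$change, node_key(rows$layer, rows$id))
  if (!is.null(drtfs) && nrow(drtfs) > 0) {
    ch[node_key("tf", drtfs$tf_gene_id)] <- drtfs$activity_change
  }
  ch
}

#' Classify differentially regulated reactions
#'
#' Per reaction, collect the set E of edge signs arriving from the Enzyme
#' Protein layer and the set M of signs from the Metabolite layer
#' (allosteric edges; mass-action too when the network was built with
#' `mass_action_signed`). All signs activating -> `activated`; all
#' inhibiting -> `inhibited`; E and M each single-signed but opposing across
#' the two layers -> `controversial`; opposing signs within one layer ->
#' `mixed_within_layer` (folded into `controversial` when the network was
#' built with `fold_mixed`); no signed edges -> `unclassified`.
#'
#' @param net a `transomic_network`.
#' @return tibble with `reaction_id` and `class`.
#' @export
classify_reactions <- function(net) {
  metab_types <- c("allosteric", if (isTRUE(net$mass_action_signed))
    "mass_action")
  rx_edges <- net$edges |>
    filter(.data$target_layer == "reaction",
           .data$type %in% c("enzyme_reaction", metab_types))
  rx_ids <- sort(unique(net$nodes$id[net$nodes$layer == "reaction"]))
  cls <- map_chr(rx_ids, function(r) {
    e <- unique(rx_edges$sign[rx_edges$target == r &
                                rx_edges$source_layer == "enzyme_protein"])
    m <- unique(rx_edges$sign[rx_edges$target == r &
                                rx_edges$source_layer == "metabolite"])
    if (length(e) == 0 && length(m) == 0) return("unclassified")
    if (length(e) > 1 || length(m) > 1) {
      return(if (isTRUE(net$fold_mixed)) "controversial"
             else "mixed_within_layer")
    }
    signs <- unique(c(e, m))
    if (length(signs) == 1) {
      return(if (signs == "activating") "activated" else "inhibited")
    }
    "controversial"
  })
  tibble(reaction_id = rx_ids, class = cls)
}

#' Per-layer node and per-type edge tallies
#'
#' @param net a `transomic_network`.
#' @return list of two tibbles: `nodes` (`layer`, `increased`, `decreased`)
#'   and `edges` (`type`, `activating`, `inhibiting`).
#' @export
layer_counts <- function(net) {
  nodes <- tidyr::crossing(layer = NETWORK_LAYERS,
                           change = c("increased", "decreased")) |>
    left_join(net$nodes |> count(.data$layer, .data$change),
              by = c("layer", "change")) |>
    mutate(n = tidyr::replace_na(.data$n, 0L)) |>
    tidyr::pivot_wider(names_from = "change", values_from = "n") |>
    mutate(layer = factor(.data$layer, levels = NETWORK_LAYERS)) |>
    arrange(.data$layer)
  edges <- tidyr::crossing(type = EDGE_TYPES,
                           sign = c("activating", "inhibiting")) |>
    left_join(net$edges |> count(.data$type, .data$sign),
              by = c("type", "sign")) |>
    mutate(n = tidyr::replace_na(.data$n, 0L)) |>
    tidyr::pivot_wider(names_from = "sign", values_from = "n")
  list(nodes = nodes, edges = edges)
}

#' Restrict a network to the reactions of given pathways
#'
#' Keeps the pathway's reactions and every upstream node that retains at
#' least one edge chain into the kept reactions (transitively up to the
#' Insulin Signal layer); metabolite edges are restricted likewise.
#'
#' @param net a `transomic_network`.
#' @param kb the `knowledge_base` the network was built from.
#' @param pathway_ids pathway IDs to keep.
#' @return a `transomic_network`.
#' @export
extract_pathway_subnetwork <- function(net, kb, pathway_ids) {
  unknown <- setdiff(pathway_ids, kb$pathways$pathway_id)
  assert_that(length(unknown) == 0,
              paste0("unknown pathway(s): ", paste(unknown, collapse = ", ")))
  keep_rx <- unique(unlist(
    kb$pathways$reaction_ids[kb$pathways$pathway_id %in% pathway_ids]))
  e <- net$edges
  e_rx <- e |> filter(.data$target_layer == "reaction",
                      .data$target %in% keep_rx)
  keep_prot <- unique(e_rx$source[e_rx$source_layer == "enzyme_protein"])
  e_gp <- e |> filter(.data$type == "gene_protein",
                      .data$target %in% keep_prot)
  e_tf <- e |> filter(.data$type == "tf_gene",
                      .data$target %in% unique(e_gp$source))
  e_kin <- e |> filter(.data$type == "kinase_tf",
                       .data$target %in% unique(e_tf$source))
  sub_edges <- bind_rows(e_kin, e_tf, e_gp, e_rx)
  keep_keys <- unique(c(node_key(sub_edges$source_layer, sub_edges$source),
                        node_key(sub_edges$target_layer, sub_edges$target)))
  nodes <- net$nodes |>
    filter(node_key(.data$layer, .data$id) %in% keep_keys)
  out <- net
  out$nodes <- nodes
  out$edges <- sub_edges
  out$reaction_class <- classify_reactions(out)
  out
}

#' @export
print.transomic_network <- function(x, ...) {
  cat(sprintf("<transomic_network: %s, %d nodes, %d edges, %d reactions>\n",
              x$compartment, nrow(x$nodes), nrow(x$edges),
              nrow(x$reaction_class)))
  if (nrow(x$reaction_class) > 0) {
    print(table(x$reaction_class$class))
  }
  invisible(x)
}

#' @method tidy transomic_network
#' @export
tidy.transomic_network <- function(x, ...) {
  x$edges |> mutate(compartment = x$compartment, .before = 1)
}

#' @method glance transomic_network
#' @export
glance.transomic_network <- function(x, ...) {
  cf <- if (nrow(x$reaction_class) > 0)
    controversial_fraction(sum(x$reaction_class$class == "controversial"),
                           nrow(x$reaction_class))$percent else NA_real_
  tibble(compartment = x$compartment,
         n_nodes = nrow(x$nodes),
         n_edges = nrow(x$edges),
         n_reactions = nrow(x$reaction_class),
         n_activated = sum(x$reaction_class$class == "activated"),
         n_inhibited = sum(x$reaction_class$class == "inhibited"),
         n_controversial = sum(x$reaction_class$class == "controversial"),
         pct_controversial = cf)
}

#' Plot node and edge tallies of a trans-omic network
#'
#' Bar panels of increased/decreased nodes per layer and
#' activating/inhibiting edges per regulation type (the summary displayed
#' alongside the layered network).
#'
#' @param object a `transomic_network`.
#' @param ... unused.
#' @return a ggplot object.
#' @method autoplot transomic_network
#' @export
autoplot.transomic_network <- function(object, ...) {
  lc <- layer_counts(object)
  dat <- bind_rows(
    lc$nodes |>
      tidyr::pivot_longer(c("increased", "decreased"),
                          names_to = "direction", values_to = "n") |>
      mutate(panel = "nodes per layer", item = as.character(.data$layer)),
    lc$edges |>
      tidyr::pivot_longer(c("activating", "inhibiting"),
                          names_to = "direction", values_to = "n") |>
      mutate(panel = "edges per type", item = .data$type))
  ggplot(dat, aes(x = .data$item, y = .data$n, fill = .data$direction)) +
    geom_col(position = "dodge") +
    facet_wrap(~panel, scales = "free") +
    scale_fill_manual(values = c(increased = "#c23b22", decreased = "#3b6fc2",
                                 activating = "#c23b22",
                                 inhibiting = "#3b6fc2")) +
    labs(x = NULL, y = "count",
         title = paste("Trans-omic network summary:", object$compartment)) +
    theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Write a trans-omic network to disk
#'
#' GraphML and JSON exports round-trip losslessly through [read_network()];
#' SIF encodes the sign in the interaction token (`activates`/`inhibits`).
#' Node identity is qualified as `layer:id` so molecules measured in
#' several layers stay distinct.
#'
#' @param net a `transomic_network`.
#' @param path output path.
#' @param format `"json"`, `"graphml"` or `"sif"`.
#' @return `path`, invisibly.
#' @export
write_network <- function(net, path, format = c("json", "graphml", "sif")) {
  format <- tryCatch(match.arg(format),
                     error = function(e)
                       config_error(paste0("unknown network format: ",
                                           format[1])))
  if (format == "json") {
    jsonlite::write_json(list(
      compartment = net$compartment,
      mass_action_signed = isTRUE(net$mass_action_signed),
      fold_mixed = isTRUE(net$fold_mixed),
      nodes = net$nodes, edges = net$edges,
      reaction_class = net$reaction_class
    ), path, dataframe = "columns", auto_unbox = TRUE, null = "null",
    na = "null")
  } else if (format == "graphml") {
    cls <- setNames(net$reaction_class$class, net$reaction_class$reaction_id)
    nodes <- net$nodes |>
      mutate(name = node_key(.data$layer, .data$id),
             change = ifelse(is.na(.data$change),
                             unname(cls[.data$id]), .data$change))
    edges_df <- net$edges |>
      mutate(from = node_key(.data$source_layer, .data$source),
             to = node_key(.data$target_layer, .data$target)) |>
      select("from", "to", "type", "mode", "sign")
    # "id" is reserved by the GraphML format; store the molecule ID as its
    # own attribute
    g <- igraph::graph_from_data_frame(
      edges_df, directed = TRUE,
      vertices = nodes |> select("name", "layer", molecule = "id", "change"))
    g <- igraph::set_graph_attr(g, "compartment", net$compartment)
    g <- igraph::set_graph_attr(g, "mass_action_signed",
                                as.character(isTRUE(net$mass_action_signed)))
    g <- igraph::set_graph_attr(g, "fold_mixed",
                                as.character(isTRUE(net$fold_mixed)))
    igraph::write_graph(g, path, format = "graphml")
  } else {
    token <- ifelse(net$edges$sign == "activating", "activates", "inhibits")
    writeLines(paste(net$edges$source, token, net$edges$target, sep = "\t"),
               path)
  }
  invisible(path)
}

#' @rdname write_network
#' @export
read_network <- function(path, format = c("json", "graphml")) {
  format <- match.arg(format)
  if (format == "json") {
    raw <- jsonlite::read_json(path, simplifyVector = TRUE)
    nodes <- as_tibble(raw$nodes)
    if (!"change" %in% names(nodes)) nodes$change <- NA_character_
    net <- structure(list(compartment = raw$compartment,
                          nodes = nodes,
                          edges = as_tibble(raw$edges),
                          reaction_class = as_tibble(raw$reaction_class),
                          mass_action_signed = isTRUE(raw$mass_action_signed),
                          fold_mixed = isTRUE(raw$fold_mixed)),
                     class = "transomic_network")
  } else {
    g <- igraph::read_graph(path, format = "graphml")
    vd <- igraph::as_data_frame(g, what = "vertices")
    ed <- igraph::as_data_frame(g, what = "edges")
    nodes <- tibble(id = vd$molecule, layer = vd$layer,
                    change = ifelse(vd$layer == "reaction", NA_character_,
                                    vd$change))
    strip <- function(k) sub("^[^:]*:", "", k)
    edges <- tibble(source = strip(ed$from),
                    source_layer = sub(":.*$", "", ed$from),
                    target = strip(ed$to),
                    target_layer = sub(":.*$", "", ed$to),
                    type = ed$type, mode = ed$mode, sign = ed$sign)
    net <- structure(list(
      compartment = igraph::graph_attr(g, "compartment"),
      nodes = nodes |> arrange(.data$layer, .data$id),
      edges = edges |> arrange(.data$type, .data$source, .data$target),
      reaction_class = NULL,
      mass_action_signed =
        identical(igraph::graph_attr(g, "mass_action_signed"), "TRUE"),
      fold_mixed = identical(igraph::graph_attr(g, "fold_mixed"), "TRUE")),
      class = "transomic_network")
    net$reaction_class <- classify_reactions(net)
  }
  net
}
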