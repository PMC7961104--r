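test_that("network assembly handles empty and minimal inputs", {
  kb <- tiny_kb()
  empty_diff <- list(protein = make_diff(character(), character(), "protein"))
  net <- build_network(empty_diff, NULL, transomix:::empty_edges(), kb,
                       "liver")
  expect_equal(nrow(net$nodes), 0)
  expect_equal(nrow(net$edges), 0)
  expect_equal(nrow(net$reaction_class), 0)

  # one increased DEME catalysing one reaction -> 2 nodes, 1 edge
  deps <- make_diff("E3", "increased", "protein")
  edges <- enzyme_reaction_edges(deps, kb)
  net2 <- build_network(list(protein = deps), NULL, edges, kb, "liver")
  expect_equal(nrow(net2$nodes), 2)
  expect_equal(nrow(net2$edges), 1)
  expect_identical(net2$reaction_class$class, "activated")
})

test_that("an edge referencing a non-differential node is an assembly error", {
  kb <- tiny_kb()
  deps <- make_diff("E3", "increased", "protein")
  rogue <- tibble::tibble(source = "Eghost", source_layer = "enzyme_protein",
                          target = "R4", target_layer = "reaction",
                          type = "enzyme_reaction", mode = "activation",
                          sign = "activating")
  expect_error(build_network(list(protein = deps), NULL, rogue, kb, "liver"),
               "Eghost")
})

test_that("reaction classification covers all rule branches", {
  mknet <- function(edges, fold_mixed = FALSE) {
    structure(list(compartment = "liver",
                   nodes = tibble::tibble(
                     id = unique(edges$target), layer = "reaction",
                     change = NA_character_),
                   edges = edges, reaction_class = NULL,
                   mass_action_signed = FALSE, fold_mixed = fold_mixed),
              class = "transomic_network")
  }
  e <- function(src, slayer, sign, type = NULL) {
    tibble::tibble(source = src, source_layer = slayer, target = "R1",
                   target_layer = "reaction",
                   type = type %||%
                     ifelse(slayer == "metabolite", "allosteric",
                            "enzyme_reaction"),
                   mode = "activation", sign = sign)
  }
  `%||%` <- function(a, b) if (is.null(a)) b else a
  # enzyme-only activating
  expect_identical(classify_reactions(mknet(e("E1", "enzyme_protein",
                                              "activating")))$class,
                   "activated")
  # all inhibiting across both layers
  both_inh <- dplyr::bind_rows(e("E1", "enzyme_protein", "inhibiting"),
                               e("A1", "metabolite", "inhibiting"))
  expect_identical(classify_reactions(mknet(both_inh))$class, "inhibited")
  # opposing input across the two layers -> controversial
  cross <- dplyr::bind_rows(e("E1", "enzyme_protein", "activating"),
                            e("A1", "metabolite", "inhibiting"))
  expect_identical(classify_reactions(mknet(cross))$class, "controversial")
  # opposing input within one layer -> mixed_within_layer
  within <- dplyr::bind_rows(e("E1", "enzyme_protein", "activating"),
                             e("E2", "enzyme_protein", "inhibiting"))
  expect_identical(classify_reactions(mknet(within))$class,
                   "mixed_within_layer")
  # ... unless folded into controversial by configuration
  expect_identical(classify_reactions(mknet(within, fold_mixed = TRUE))$class,
                   "controversial")
  # unsigned mass-action context does not classify
  ma_only <- e("A1", "metabolite", "activating", type = "mass_action")
  expect_identical(classify_reactions(mknet(ma_only))$class, "unclassified")
  # classification is invariant to edge input order
  shuffled <- mknet(cross[2:1, ])
  expect_identical(classify_reactions(shuffled)$class, "controversial")
})

test_that("reaction classes form a partition of the reaction set", {
  for (seed in 1:5) {
    st <- generate_study(small_config(seed = 100 + seed),
                         simulate_tables = FALSE)
    net <- pipeline_network_from_truth(st$ground_truth$planted$liver,
                                       st$kb, "liver")
    cls <- net$reaction_class$class
    expect_equal(sum(cls %in% c("activated", "inhibited", "controversial",
                                "mixed_within_layer", "unclassified")),
                 length(cls))
    expect_false(any(duplicated(net$reaction_class$reaction_id)))
    # every reaction node carries at least one signed edge
    rx_edges <- net$edges[net$edges$target_layer == "reaction", ]
    expect_true(all(net$reaction_class$reaction_id %in% rx_edges$target))
  }
})

test_that("layer counts tally nodes and edges deterministically", {
  kb <- tiny_kb()
  deps <- make_diff(c("E1", "E3"), c("increased", "decreased"), "protein")
  edges <- enzyme_reaction_edges(deps, kb)
  net <- build_network(list(protein = deps), NULL, edges, kb, "liver")
  lc <- layer_counts(net)
  ep <- lc$nodes[lc$nodes$layer == "enzyme_protein", ]
  expect_equal(ep$increased, 1L)
  expect_equal(ep$decreased, 1L)
  er <- lc$edges[lc$edges$type == "enzyme_reaction", ]
  expect_equal(er$activating, 2L)  # E1 -> R1, R2
  expect_equal(er$inhibiting, 1L)  # E3 -> R4
  expect_equal(sum(lc$nodes$increased + lc$nodes$decreased),
               sum(!is.na(net$nodes$change)))
  expect_equal(sum(lc$edges$activating + lc$edges$inhibiting),
               nrow(net$edges))
  # empty network -> all zeros
  net0 <- build_network(list(protein = make_diff(character(), character(),
                                                 "protein")),
                        NULL, transomix:::empty_edges(), kb, "liver")
  lc0 <- layer_counts(net0)
  expect_true(all(lc0$nodes$increased == 0 & lc0$nodes$decreased == 0))
  expect_true(all(lc0$edges$activating == 0 & lc0$edges$inhibiting == 0))
})

test_that("pathway subnetwork extraction keeps only connected upstream", {
  st <- generate_study(small_config(seed = 55), simulate_tables = FALSE)
  net <- pipeline_network_from_truth(st$ground_truth$planted$liver, st$kb,
                                     "liver")
  all_pw <- st$kb$pathways$pathway_id
  # selecting every pathway is the identity
  expect_same_network(extract_pathway_subnetwork(net, st$kb, all_pw), net)
  # empty selection empties the network
  sub0 <- extract_pathway_subnetwork(net, st$kb, character())
  expect_equal(nrow(sub0$nodes), 0)
  # single pathway: reactions restricted to it, upstream retained iff
  # connected
  pw <- all_pw[1]
  keep <- st$kb$pathways$reaction_ids[[1]]
  sub <- extract_pathway_subnetwork(net, st$kb, pw)
  expect_true(all(sub$reaction_class$reaction_id %in% keep))
  ep_sources <- sub$edges$source[sub$edges$source_layer == "enzyme_protein"]
  expect_true(all(sub$nodes$id[sub$nodes$layer == "enzyme_protein"] %in%
                    ep_sources))
  expect_error(extract_pathway_subnetwork(net, st$kb, "nope"), "nope")
})

test_that("tidy/glance/autoplot expose the network as tables and figure", {
  st <- generate_study(small_config(seed = 56), simulate_tables = FALSE)
  net <- pipeline_network_from_truth(st$ground_truth$planted$liver, st$kb,
                                     "liver")
  td <- tidy(net)
  expect_s3_class(td, "tbl_df")
  expect_identical(td$compartment[1], "liver")
  gl <- glance(net)
  expect_equal(gl$n_edges, nrow(net$edges))
  expect_equal(gl$n_reactions, nrow(net$reaction_class))
  p <- autoplot(net)
  expect_s3_class(p, "ggplot")
})
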