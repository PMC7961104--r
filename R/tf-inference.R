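#' TF motif enrichment in a DEG set
#'
#' One-tailed hypergeometric (upper tail, equivalently one-sided Fisher)
#' test per motif: the population is the background gene universe, successes
#' are the motif's targets within the background, draws are the DEGs, and
#' the p value is P(X >= k) for the observed overlap k. q values are
#' Benjamini-Hochberg across motifs.
#'
#' @param deg_set character vector of differentially expressed genes, a
#'   subset of `background`.
#' @param background character vector: all genes detected in the organ.
#' @param motifs motif tibble (`tf_gene_id`, `motif_id`, list-col
#'   `target_ids`), e.g. `kb$motifs`.
#' @return tibble with `tf_gene_id`, `motif_id`, `n_targets`, `k`, `p`, `q`.
#' @export
motif_enrichment <- function(deg_set, background, motifs) {
  assert_that(all(deg_set %in% background),
              "deg_set must be a subset of background")
  targets_bg <- map(motifs$target_ids, intersect, background)
  skip <- lengths(targets_bg) == 0
  if (any(skip)) {
    warn(paste0("motif(s) with no targets in background skipped: ",
                paste(motifs$motif_id[skip], collapse = ", ")))
  }
  out <- motifs[!skip, c("tf_gene_id", "motif_id")]
  targets_bg <- targets_bg[!skip]
  N <- length(background)
  n_deg <- length(deg_set)
  out$n_targets <- lengths(targets_bg)
  out$k <- map_dbl(targets_bg, ~ length(intersect(.x, deg_set)))
  out$p <- if (n_deg == 0) rep(1, nrow(out)) else
    phyper(out$k - 1, out$n_targets, N - out$n_targets, n_deg,
           lower.tail = FALSE)
  out$q <- bh_qvalues(out$p)
  out
}

#' Differentially expressed TFs (DETFs)
#'
#' A TF is a DETF when its motif is enriched in a DEG set (q below
#' `q_threshold`) and its own gene is itself a DEG; its activity change is
#' its expression change.
#'
#' @param enrichment output of [motif_enrichment()] (run against one DEG
#'   direction).
#' @param deg_results diff-result tibble for the transcript layer.
#' @param enriched_in label recorded on the result (`"increased_degs"` or
#'   `"decreased_degs"`).
#' @param q_threshold motif-enrichment significance threshold (default 0.1).
#' @return tibble of DRTF records with `origin = "DETF"`.
#' @export
identify_detfs <- function(enrichment, deg_results,
                           enriched_in = c("increased_degs", "decreased_degs"),
                           q_threshold = 0.1) {
  enriched_in <- match.arg(enriched_in)
  degs <- deg_results |> filter(.data$class != "unchanged")
  enrichment |>
    filter(.data$q < q_threshold) |>
    inner_join(degs |> select("feature_id", "class"),
               by = c(tf_gene_id = "feature_id")) |>
    mutate(origin = "DETF",
           activity_change = .data$class,
           enriched_in = enriched_in) |>
    select("tf_gene_id", "origin", "activity_change", "enriched_in",
           enrichment_p = "p", enrichment_q = "q")
}

#' Differentially phosphorylated TFs (DPTFs)
#'
#' Phospho-TFs among the DPPs whose motif is enriched in a DEG set. The
#' activity change combines the phospho change with the annotated effect of
#' phosphorylation on the TF: an inactivating phosphorylation (Foxo1-like
#' nuclear export) inverts the sign, so increased phospho means decreased
#' activity. TFs with an unknown phospho effect are excluded with a warning.
#'
#' @param dpps diff-result tibble from [phospho_ratio_test()].
#' @param kinase_tf kinase-TF tibble (`kinase_id`, `tf_id`,
#'   `phospho_effect`), e.g. `kb$kinase_tf`.
#' @param enrichment output of [motif_enrichment()].
#' @param enriched_in direction label of the DEG set tested.
#' @param q_threshold motif-enrichment threshold (default 0.1).
#' @return tibble of DRTF records with `origin = "DPTF"`.
#' @export
identify_dptfs <- function(dpps, kinase_tf, enrichment,
                           enriched_in = c("increased_degs", "decreased_degs"),
                           q_threshold = 0.1) {
  enriched_in <- match.arg(enriched_in)
  effects <- kinase_tf |> distinct(.data$tf_id, .data$phospho_effect)
  bad <- effects$tf_id[effects$phospho_effect %nin%
                         c("activating", "inactivating")]
  if (length(bad) > 0) {
    warn(paste0("TF(s) with unknown phospho effect excluded: ",
                paste(unique(bad), collapse = ", ")))
    effects <- effects |> filter(.data$tf_id %nin% bad)
  }
  hits <- dpps |>
    filter(.data$class != "unchanged") |>
    inner_join(effects, by = c(feature_id = "tf_id"),
               relationship = "many-to-many") |>
    inner_join(enrichment |> filter(.data$q < q_threshold),
               by = c(feature_id = "tf_gene_id"))
  if (nrow(hits) == 0) return(empty_drtfs())
  hits |>
    mutate(
      origin = "DPTF",
      activity_change = ifelse(.data$phospho_effect == "inactivating",
                               flip_change(.data$class), .data$class),
      enriched_in = enriched_in) |>
    select(tf_gene_id = "feature_id", "origin", "activity_change",
           "enriched_in", enrichment_p = "p.y", enrichment_q = "q.y")
}

empty_drtfs <- function() {
  tibble(tf_gene_id = character(), origin = character(),
         activity_change = character(), enriched_in = character(),
         enrichment_p = numeric(), enrichment_q = numeric())
}

flip_change <- function(x) {
  ifelse(x == "increased", "decreased",
         ifelse(x == "decreased", "increased", x))
}

#' Kinase-to-TF differential regulations
#'
#' Signed edges from differentially phosphorylated kinases (Insulin Signal
#' layer) to differentially regulated TFs, for pairs present in the
#' kinase-TF table. The kinase's phospho change is treated as its activity
#' change and combined with an activation mode.
#'
#' @param dpps diff-result tibble of phospho pairs (kinases keyed by
#'   phospho feature ID).
#' @param drtfs DRTF tibble ([identify_detfs()] / [identify_dptfs()] rows).
#' @param kinase_tf kinase-TF tibble.
#' @return a regulation-edge tibble (see [combine_signs()] for the sign
#'   rule).
#' @export
kinase_tf_edges <- function(dpps, drtfs, kinase_tf) {
  diff_kinases <- dpps |> filter(.data$class != "unchanged")
  hits <- kinase_tf |>
    inner_join(diff_kinases |> select("feature_id", "class"),
               by = c(kinase_id = "feature_id")) |>
    semi_join(drtfs, by = c(tf_id = "tf_gene_id"))
  if (nrow(hits) == 0) return(empty_edges())
  hits |>
    mutate(
      source = .data$kinase_id, source_layer = "insulin_signal",
      target = .data$tf_id, target_layer = "tf",
      type = "kinase_tf", mode = "activation",
      sign = combine_signs(.data$class, "activation")) |>
    select("source", "source_layer", "target", "target_layer",
           "type", "mode", "sign") |>
    distinct()
}
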