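#' Run the four-stage trans-omic pipeline on a study bundle
#'
#' End-to-end orchestration: (1) per-layer differential molecules
#' (negative-binomial exact test + Storey q for transcripts; Welch + Storey
#' for proteins and polar metabolites; Welch + Benjamini-Hochberg for
#' lipids; phospho/total ratio tests), (2) TF inference (motif enrichment
#' per DEG direction, DETFs, DPTFs, kinase edges), (3) signed differential
#' regulations and per-organ network assembly with reaction classification,
#' (4) blood comparison (shared DEMs, fold-change correlations, optional
#' cycle reports) and summary statistics. Deterministic given the study
#' bundle; optionally writes all result tables, networks, a JSON summary
#' and a manifest (parameter echo plus output checksums) to `out_dir`.
#'
#' @param study a study bundle as produced by [generate_study()]: list with
#'   `tables` (per compartment, per layer), `designs` (per layer) and `kb`.
#' @param q_threshold molecule significance threshold (default 0.1).
#' @param fisher_alpha DRTF-pathway significance threshold on q (default
#'   0.01).
#' @param mass_action_signed,fold_mixed sign-convention flags passed to
#'   [build_network()].
#' @param treat_reversible passed to [mass_action_edges()].
#' @param cycles optional list of `cycle_definition`s to report on (e.g.
#'   [built_in_cycles()]).
#' @param out_dir optional output directory.
#' @return list with `diff`, `enrichment`, `drtfs`, `edges`, `networks`,
#'   `stats`, `interorgan`, `params`.
#' @export
run_pipeline <- function(study, q_threshold = 0.1, fisher_alpha = 0.01,
                         mass_action_signed = FALSE, fold_mixed = FALSE,
                         treat_reversible = "substrates_only",
                         cycles = NULL, out_dir = NULL) {
  kb <- study$kb
  organs <- setdiff(names(study$tables), "blood")
  assert_that(length(organs) >= 1, "study has no organ compartments")

  diff <- lapply(names(study$tables), function(comp) {
    tabs <- study$tables[[comp]]
    out <- list()
    for (layer in intersect(c("transcript", "protein", "metabolite", "lipid"),
                            names(tabs))) {
      q_method <- if (layer == "lipid") "bh" else "storey"
      out[[layer]] <- diff_molecules(tabs[[layer]], study$designs[[layer]],
                                     q_method = q_method,
                                     q_threshold = q_threshold)
    }
    if ("phospho" %in% names(tabs)) {
      out$phospho <- phospho_ratio_test(tabs$phospho, study$designs$phospho,
                                        q_threshold = q_threshold)
    }
    out
  })
  names(diff) <- names(study$tables)

  per_organ <- lapply(organs, function(comp) {
    d <- diff[[comp]]
    degs <- d$transcript
    background <- degs$feature_id
    deg_up <- degs$feature_id[degs$class == "increased"]
    deg_down <- degs$feature_id[degs$class == "decreased"]
    enr <- list(
      increased_degs = suppressWarnings(
        motif_enrichment(deg_up, background, kb$motifs)),
      decreased_degs = suppressWarnings(
        motif_enrichment(deg_down, background, kb$motifs)))
    drtfs <- bind_rows(
      identify_detfs(enr$increased_degs, degs, "increased_degs", q_threshold),
      identify_detfs(enr$decreased_degs, degs, "decreased_degs", q_threshold),
      if (!is.null(d$phospho)) bind_rows(
        identify_dptfs(d$phospho, kb$kinase_tf, enr$increased_degs,
                       "increased_degs", q_threshold),
        identify_dptfs(d$phospho, kb$kinase_tf, enr$decreased_degs,
                       "decreased_degs", q_threshold))) |>
      distinct(.data$tf_gene_id, .data$origin, .data$activity_change,
               .keep_all = TRUE)
    edges <- bind_rows(
      if (!is.null(d$phospho)) kinase_tf_edges(d$phospho, drtfs,
                                               kb$kinase_tf),
      tf_gene_edges(drtfs, degs, kb),
      gene_protein_edges(degs, d$protein, kb$gene_protein_map),
      enzyme_reaction_edges(d$protein, kb),
      suppressWarnings(allosteric_edges(d$metabolite, kb)),
      mass_action_edges(d$metabolite, kb, treat_reversible))
    net <- build_network(
      d[intersect(c("transcript", "protein", "metabolite", "phospho"),
                  names(d))],
      drtfs, edges, kb, comp,
      mass_action_signed = mass_action_signed, fold_mixed = fold_mixed)
    stats <- list(
      layer_counts = layer_counts(net),
      controversial = if (nrow(net$reaction_class) > 0)
        controversial_fraction(net) else NULL,
      pathway_summary = pathway_regulation_percentages(net, kb),
      drtf_pathways = drtf_pathway_enrichment(net, kb, fisher_alpha))
    list(enrichment = enr, drtfs = drtfs, edges = edges, network = net,
         stats = stats)
  })
  names(per_organ) <- organs

  dems <- lapply(diff[names(diff)], function(d) d$metabolite)
  dems <- dems[!vapply(dems, is.null, TRUE)]
  fc_of <- function(d) setNames(d$log2fc, d$feature_id)
  correlations <- NULL
  if ("blood" %in% names(diff)) {
    blood_dems <- diff$blood$metabolite
    correlations <- bind_rows(lapply(organs, function(comp) {
      restrict <- blood_dems$feature_id[blood_dems$class != "unchanged"]
      cc <- tryCatch(
        crosscompartment_correlation(fc_of(diff[[comp]]$metabolite),
                                     fc_of(blood_dems),
                                     restrict_to = restrict),
        transomix_validation_error = function(e) list(r = NA_real_, n = 0L))
      tibble(organ = comp, blood_vs = "blood", r = cc$r, n = cc$n)
    }))
  }
  interorgan <- list(
    common_dems = common_dems(dems),
    correlations = correlations,
    dem_classes = dem_class_summary(dems, kb$metabolite_class),
    cycle_reports = if (!is.null(cycles))
      lapply(cycles, cycle_report, diff_by_compartment = diff))

  results <- list(
    diff = diff,
    enrichment = lapply(per_organ, `[[`, "enrichment"),
    drtfs = lapply(per_organ, `[[`, "drtfs"),
    edges = lapply(per_organ, `[[`, "edges"),
    networks = lapply(per_organ, `[[`, "network"),
    stats = lapply(per_organ, `[[`, "stats"),
    interorgan = interorgan,
    params = list(q_threshold = q_threshold, fisher_alpha = fisher_alpha,
                  mass_action_signed = mass_action_signed,
                  fold_mixed = fold_mixed,
                  treat_reversible = treat_reversible))
  if (!is.null(out_dir)) write_run_dir(results, out_dir)
  results
}

write_run_dir <- function(results, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  written <- character()
  for (comp in names(results$diff)) {
    for (layer in names(results$diff[[comp]])) {
      f <- file.path(out_dir, sprintf("diff_%s_%s.tsv", comp, layer))
      write_diff_table(results$diff[[comp]][[layer]], f)
      written <- c(written, f)
    }
  }
  for (comp in names(results$networks)) {
    f_e <- file.path(out_dir, sprintf("edges_%s.tsv", comp))
    readr::write_tsv(results$edges[[comp]], f_e)
    f_n <- file.path(out_dir, sprintf("network_%s.json", comp))
    write_network(results$networks[[comp]], f_n, "json")
    written <- c(written, f_e, f_n)
  }
  f_sum <- file.path(out_dir, "summary.json")
  jsonlite::write_json(make_report(results), f_sum, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, na = "null")
  written <- c(written, f_sum)
  manifest <- list(params = results$params,
                   files = lapply(setNames(nm = basename(written)),
                                  function(b) unname(
                                    tools::md5sum(file.path(out_dir, b)))))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(out_dir)
}

#' Aggregate pipeline results into a single summary
#'
#' Collects per-organ layer counts, controversial fractions, pathway
#' regulation percentages, significant DRTF-pathway associations, shared
#' DEMs, cross-compartment correlations and cycle verdicts into one
#' JSON-serialisable list.
#'
#' @param results output of [run_pipeline()].
#' @return a named list.
#' @export
make_report <- function(results) {
  needed <- c("networks", "stats", "interorgan", "params")
  missing <- setdiff(needed, names(results))
  assert_that(length(missing) == 0,
              paste0("incomplete run: missing ", paste(missing,
                                                       collapse = ", ")))
  organs <- lapply(names(results$networks), function(comp) {
    st <- results$stats[[comp]]
    ctr <- st$controversial
    list(
      compartment = comp,
      nodes_per_layer = st$layer_counts$nodes,
      edges_per_type = st$layer_counts$edges,
      n_reactions = nrow(results$networks[[comp]]$reaction_class),
      reaction_classes = as.list(table(
        results$networks[[comp]]$reaction_class$class)),
      controversial = if (!is.null(ctr))
        list(n = ctr$n_controversial, total = ctr$n_total,
             percent = round_half_up(ctr$percent, 1)),
      pathway_summary = st$pathway_summary,
      significant_drtf_pathways = st$drtf_pathways |>
        filter(.data$significant) |>
        select("tf_gene_id", "pathway_id", "count", "q"))
  })
  names(organs) <- names(results$networks)
  list(
    params = results$params,
    organs = organs,
    common_dems = results$interorgan$common_dems |>
      select("compartments", "direction", "n"),
    correlations = results$interorgan$correlations,
    cycle_verdicts = if (!is.null(results$interorgan$cycle_reports))
      lapply(results$interorgan$cycle_reports,
             function(cr) list(cycle = cr$cycle, verdicts = cr$verdicts)))
}
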