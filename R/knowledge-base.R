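#' Construct a knowledge base
#'
#' The knowledge base collects the reference tables that turn differential
#' molecules into signed regulations: the reaction map (enzyme, substrates,
#' products, reversibility, pathway membership), the allosteric regulator
#' table (activator/inhibitor modes), the TF motif-to-target table, the
#' kinase-to-TF table with the sign of the phosphorylation's effect on TF
#' activity, the gene-to-protein ID map, the metabolite class map and the
#' pathway sets. Multi-valued cells in list-columns hold character vectors.
#'
#' @param reactions tibble: `reaction_id`, list-cols `enzyme_ids`,
#'   `substrate_ids`, `product_ids`, logical `reversible`, list-col
#'   `pathway_ids`.
#' @param allosteric tibble: `metabolite_id`, `enzyme_protein_id`,
#'   `mode` in `{activator, inhibitor}`.
#' @param motifs tibble: `tf_gene_id`, `motif_id`, list-col `target_ids`.
#' @param kinase_tf tibble: `kinase_id`, `tf_id`, `phospho_effect` in
#'   `{activating, inactivating}`.
#' @param gene_protein_map tibble: `gene_id`, `protein_id`.
#' @param metabolite_class tibble: `metabolite_id`, `class`.
#' @param pathways tibble: `pathway_id`, `class`, list-col `reaction_ids`.
#' @return a `knowledge_base` object.
#' @export
knowledge_base <- function(reactions, allosteric, motifs, kinase_tf,
                           gene_protein_map, metabolite_class, pathways) {
  kb <- structure(list(
    reactions = as_tibble(reactions),
    allosteric = as_tibble(allosteric),
    motifs = as_tibble(motifs),
    kinase_tf = as_tibble(kinase_tf),
    gene_protein_map = as_tibble(gene_protein_map),
    metabolite_class = as_tibble(metabolite_class),
    pathways = as_tibble(pathways),
    unmapped_enzymes = character()
  ), class = "knowledge_base")
  validate_knowledge_base(kb)
}

validate_knowledge_base <- function(kb) {
  rx <- kb$reactions
  assert_that(all(lengths(rx$enzyme_ids) >= 1),
              "every reaction needs at least one enzyme")
  both <- purrr::map2(rx$substrate_ids, rx$product_ids, intersect)
  bad <- rx$reaction_id[lengths(both) > 0]
  assert_that(length(bad) == 0,
              paste0("substrates and products overlap in reaction(s): ",
                     paste(bad, collapse = ", ")))
  badmode <- setdiff(unique(kb$allosteric$mode), c("activator", "inhibitor"))
  assert_that(length(badmode) == 0,
              paste0("allosteric mode must be activator/inhibitor, got: ",
                     paste(badmode, collapse = ", ")))
  assert_that(!any(duplicated(kb$allosteric[c("metabolite_id",
                                              "enzyme_protein_id", "mode")])),
              "duplicate (metabolite, enzyme, mode) allosteric entries")
  assert_that(all(lengths(kb$motifs$target_ids) > 0),
              "motif with empty target set")
  assert_that(!any(duplicated(kb$motifs[c("tf_gene_id", "motif_id")])),
              "duplicate (tf, motif) records")
  unknown_rx <- setdiff(unlist(kb$pathways$reaction_ids), rx$reaction_id)
  assert_that(length(unknown_rx) == 0,
              paste0("pathway references unknown reaction(s): ",
                     paste(unknown_rx, collapse = ", ")))
  # Enzymes without a gene mapping are kept but flagged, never dropped.
  kb$unmapped_enzymes <-
    setdiff(unique(unlist(rx$enzyme_ids)), kb$gene_protein_map$protein_id)
  if (length(kb$unmapped_enzymes) > 0) {
    warn(paste0(length(kb$unmapped_enzymes),
                " enzyme protein(s) missing from the gene-protein map: ",
                paste(head(kb$unmapped_enzymes, 5), collapse = ", ")))
  }
  kb
}

#' @export
print.knowledge_base <- function(x, ...) {
  cat(sprintf(paste0("<knowledge_base: %d reactions, %d allosteric entries, ",
                     "%d motifs, %d pathways>\n"),
              nrow(x$reactions), nrow(x$allosteric), nrow(x$motifs),
              nrow(x$pathways)))
  invisible(x)
}

kb_read_tsv <- function(path, required) {
  tbl <- readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                         progress = FALSE)
  missing <- setdiff(required, names(tbl))
  assert_that(length(missing) == 0,
              paste0(basename(path), ": missing column(s) ",
                     paste(missing, collapse = ", ")))
  tbl
}

read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(lengths(parts) < 3)
  assert_that(length(short) == 0,
              sprintf("GMT line %d has fewer than 3 fields", short[1]))
  tibble(
    pathway_id = map_chr(parts, 1),
    class = map_chr(parts, 2),
    reaction_ids = map(parts, ~ .x[-(1:2)])
  )
}

write_gmt <- function(pathways, path) {
  lines <- pmap(pathways[c("pathway_id", "class", "reaction_ids")],
                function(pathway_id, class, reaction_ids)
                  paste(c(pathway_id, class, reaction_ids), collapse = "\t"))
  writeLines(unlist(lines), path)
}

#' Read a knowledge base from a directory of plain-text tables
#'
#' Expects `reactions.tsv` (reaction_id, enzyme_ids, substrate_ids,
#' product_ids, reversible; comma-separated multi-value cells),
#' `allosteric.tsv`, `motifs.tsv` (targets comma-separated),
#' `kinase_tf.tsv`, `gene_protein_map.tsv`, `metabolite_class.tsv` and
#' `pathways.gmt` (pathway, class, member reaction IDs). Pathway membership
#' on each reaction is derived from the GMT file.
#'
#' @param dir directory containing the tables.
#' @return a validated `knowledge_base`.
#' @export
read_knowledge_base <- function(dir) {
  p <- function(f) file.path(dir, f)
  rx <- kb_read_tsv(p("reactions.tsv"),
                    c("reaction_id", "enzyme_ids", "substrate_ids",
                      "product_ids", "reversible"))
  pathways <- read_gmt(p("pathways.gmt"))
  membership <- pathways |>
    select("pathway_id", "reaction_ids") |>
    tidyr::unnest(cols = "reaction_ids") |>
    rename(reaction_id = "reaction_ids") |>
    group_by(.data$reaction_id) |>
    summarise(pathway_ids = list(.data$pathway_id))
  reactions <- tibble(
    reaction_id = trimws(rx$reaction_id),
    enzyme_ids = split_ids(rx$enzyme_ids),
    substrate_ids = split_ids(rx$substrate_ids),
    product_ids = split_ids(rx$product_ids),
    reversible = toupper(trimws(rx$reversible)) %in% c("TRUE", "1", "YES")
  ) |>
    left_join(membership, by = "reaction_id") |>
    mutate(pathway_ids = map(.data$pathway_ids, ~ .x %||% character()))
  al <- kb_read_tsv(p("allosteric.tsv"),
                    c("metabolite_id", "enzyme_protein_id", "mode"))
  mo <- kb_read_tsv(p("motifs.tsv"),
                    c("tf_gene_id", "motif_id", "target_gene_ids"))
  motifs <- tibble(tf_gene_id = trimws(mo$tf_gene_id),
                   motif_id = trimws(mo$motif_id),
                   target_ids = split_ids(mo$target_gene_ids))
  kt <- kb_read_tsv(p("kinase_tf.tsv"), c("kinase_id", "tf_id", "phospho_effect"))
  gp <- kb_read_tsv(p("gene_protein_map.tsv"), c("gene_id", "protein_id"))
  mc <- kb_read_tsv(p("metabolite_class.tsv"), c("metabolite_id", "class"))
  knowledge_base(reactions, al, motifs, kt, gp, mc, pathways)
}

#' Write a knowledge base to a directory of plain-text tables
#' @param kb a `knowledge_base`.
#' @param dir output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_knowledge_base <- function(kb, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(dir, f)
  rx <- kb$reactions
  readr::write_tsv(tibble(
    reaction_id = rx$reaction_id,
    enzyme_ids = join_ids(rx$enzyme_ids),
    substrate_ids = join_ids(rx$substrate_ids),
    product_ids = join_ids(rx$product_ids),
    reversible = rx$reversible
  ), p("reactions.tsv"))
  readr::write_tsv(kb$allosteric, p("allosteric.tsv"))
  readr::write_tsv(tibble(
    tf_gene_id = kb$motifs$tf_gene_id,
    motif_id = kb$motifs$motif_id,
    target_gene_ids = join_ids(kb$motifs$target_ids)
  ), p("motifs.tsv"))
  readr::write_tsv(kb$kinase_tf, p("kinase_tf.tsv"))
  readr::write_tsv(kb$gene_protein_map, p("gene_protein_map.tsv"))
  readr::write_tsv(kb$metabolite_class, p("metabolite_class.tsv"))
  write_gmt(kb$pathways, p("pathways.gmt"))
  invisible(dir)
}

# reaction_id -> tibble(reaction_id, enzyme_id) long map
reaction_enzyme_long <- function(kb) {
  kb$reactions |>
    select("reaction_id", "enzyme_ids") |>
    tidyr::unnest(cols = "enzyme_ids") |>
    rename(enzyme_id = "enzyme_ids")
}
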