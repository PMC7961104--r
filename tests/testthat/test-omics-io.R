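test_that("omics tables round-trip through TSV with validation", {
  tbl <- omics_table(
    tibble::tibble(feature_id = c("Gck", "Pklr", "Gapdh"),
                   s1 = c(1, 2, 3), s2 = c(4, 5, 6),
                   s3 = c(7, 8, 9), s4 = c(0, 1, 2)),
    layer = "transcript", compartment = "liver")
  f <- withr::local_tempfile(fileext = ".tsv")
  write_omics_table(tbl, f)
  back <- read_omics_table(f, "transcript", "liver")
  expect_equal(dim(back), c(3L, 5L))
  expect_equal(as.data.frame(back), as.data.frame(tbl))
  expect_identical(table_layer(back), "transcript")
  expect_identical(table_samples(back), c("s1", "s2", "s3", "s4"))
})

test_that("omics table validation names the offending feature", {
  dup <- tibble::tibble(feature_id = c("Gck", "Gck"), s1 = c(1, 2),
                        s2 = c(3, 4))
  expect_error(omics_table(dup, "transcript", "liver"), "Gck")
  frac <- tibble::tibble(feature_id = c("Gck", "Pklr"), s1 = c(1, 2.5),
                         s2 = c(3, 4))
  expect_error(omics_table(frac, "transcript", "liver"), "integer")
  # same values are fine for an abundance layer
  expect_s3_class(omics_table(frac, "protein", "liver"), "omics_table")
  neg <- tibble::tibble(feature_id = "Gck", s1 = -1, s2 = 2)
  expect_error(omics_table(neg, "protein", "liver"), "negative")
})

test_that("strict numeric parsing reports row and column", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("feature_id\ts1\ts2", "Gck\t1\toops", "Pklr\t2\t3"), f)
  expect_error(read_omics_table(f, "protein", "liver"),
               "row 1.*column 's2'")
  # NA cells are permitted
  writeLines(c("feature_id\ts1\ts2", "Gck\t1\tNA", "Pklr\t2\t3"), f)
  expect_true(is.na(as.data.frame(
    read_omics_table(f, "protein", "liver"))[1, "s2"]))
})

test_that("sample designs parse, validate, and reject degenerate files", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("sample_id\tcondition",
               paste0("wt", 1:5, "\tWT"),
               paste0("ob", 1:5, "\tob/ob")), f)
  d <- read_sample_design(f)
  expect_equal(nrow(d), 10)
  expect_equal(sum(d$condition == "control"), 5)
  expect_equal(d$replicate[d$condition == "case"], 1:5)

  writeLines(c("sample_id\tcondition", paste0("wt", 1:4, "\tWT")), f)
  expect_error(read_sample_design(f), "both")
  writeLines(c("sample_id\tcondition", "a\tWT", "a\tWT", "b\tob/ob",
               "c\tob/ob"), f)
  expect_error(read_sample_design(f), "duplicate")
  writeLines(c("sample_id\tcondition", "a\tmystery", "b\tob/ob"), f)
  expect_error(read_sample_design(f), "mystery")
})

test_that("knowledge bases round-trip through their TSV/GMT directory", {
  kb <- tiny_kb()
  dir <- withr::local_tempdir()
  write_knowledge_base(kb, dir)
  back <- suppressWarnings(read_knowledge_base(dir))
  expect_equal(nrow(back$reactions), 5)
  expect_equal(nrow(back$pathways), 3)
  expect_equal(back$allosteric, kb$allosteric)
  expect_equal(back$kinase_tf, kb$kinase_tf)
  expect_equal(back$motifs$target_ids, kb$motifs$target_ids)
  expect_setequal(back$reactions$reaction_id, kb$reactions$reaction_id)
  # pathway membership reconstructed from the GMT file
  got <- back$reactions$pathway_ids[back$reactions$reaction_id == "R3"]
  expect_equal(got[[1]], "pw2")
})

test_that("knowledge-base schema violations are rejected with names", {
  kb <- tiny_kb()
  dir <- withr::local_tempdir()
  write_knowledge_base(kb, dir)
  al <- readr::read_tsv(file.path(dir, "allosteric.tsv"),
                        show_col_types = FALSE)
  al$mode[1] <- "cofactor"
  readr::write_tsv(al, file.path(dir, "allosteric.tsv"))
  expect_error(suppressWarnings(read_knowledge_base(dir)), "cofactor")

  write_knowledge_base(kb, dir)
  cat("pwbad\tlipid\tR999\n", file = file.path(dir, "pathways.gmt"),
      append = TRUE)
  expect_error(suppressWarnings(read_knowledge_base(dir)), "R999")

  write_knowledge_base(kb, dir)
  cat("short_line\tonly2fields\n", file = file.path(dir, "pathways.gmt"),
      append = TRUE)
  expect_error(suppressWarnings(read_knowledge_base(dir)), "fewer than 3")
})

test_that("knowledge_base rejects overlapping substrate/product sets", {
  kb <- tiny_kb()
  rx <- kb$reactions
  rx$product_ids[[1]] <- c("P1", "S1")
  expect_error(
    knowledge_base(rx, kb$allosteric, kb$motifs, kb$kinase_tf,
                   kb$gene_protein_map, kb$metabolite_class, kb$pathways),
    "overlap.*R1")
})

test_that("unmapped enzymes are flagged, not dropped", {
  kb <- tiny_kb()
  gp <- kb$gene_protein_map[kb$gene_protein_map$protein_id != "E4", ]
  expect_warning(
    kb2 <- knowledge_base(kb$reactions, kb$allosteric, kb$motifs,
                          kb$kinase_tf, gp, kb$metabolite_class,
                          kb$pathways),
    "E4")
  expect_identical(kb2$unmapped_enzymes, "E4")
  expect_equal(nrow(kb2$reactions), 5)
})

test_that("network export round-trips in JSON and GraphML, SIF encodes sign", {
  st <- generate_study(small_config(seed = 3), simulate_tables = FALSE)
  net <- pipeline_network_from_truth(st$ground_truth$planted$liver, st$kb,
                                     "liver")
  f_json <- withr::local_tempfile(fileext = ".json")
  write_network(net, f_json, "json")
  expect_same_network(read_network(f_json, "json"), net)

  f_gml <- withr::local_tempfile(fileext = ".graphml")
  write_network(net, f_gml, "graphml")
  expect_same_network(read_network(f_gml, "graphml"), net)

  f_sif <- withr::local_tempfile(fileext = ".sif")
  one <- net
  one$edges <- net$edges[1, ]
  one$edges$source <- "A"; one$edges$target <- "B"
  one$edges$sign <- "activating"
  write_network(one, f_sif, "sif")
  expect_identical(readLines(f_sif), "A\tactivates\tB")

  expect_error(write_network(net, f_json, "dot"), "unknown network format")
})

test_that("a zero-edge network exports nodes only", {
  net <- structure(list(compartment = "liver",
                        nodes = tibble::tibble(id = "m1",
                                               layer = "metabolite",
                                               change = "increased"),
                        edges = transomix:::empty_edges(),
                        reaction_class = tibble::tibble(
                          reaction_id = character(), class = character()),
                        mass_action_signed = FALSE, fold_mixed = FALSE),
                   class = "transomic_network")
  f <- withr::local_tempfile(fileext = ".json")
  write_network(net, f, "json")
  back <- read_network(f, "json")
  expect_equal(nrow(back$nodes), 1)
  expect_equal(nrow(back$edges), 0)
})

test_that("diff tables round-trip with fixed column order and NA rendering", {
  res <- make_diff(c("b", "a", "c"), c("increased", "decreased", "unchanged"),
                   "protein")
  res$q[3] <- NA_real_
  f <- withr::local_tempfile(fileext = ".tsv")
  write_diff_table(res, f)
  header <- readLines(f, n = 1)
  expect_identical(header,
                   "feature_id\tlayer\tcompartment\tlog2fc\tstat\tdf\tp\tq\tclass")
  expect_match(readLines(f)[4], "NA")
  back <- read_diff_table(f)
  expect_equal(nrow(back), 3)
  # stable sort by q then feature id
  expect_identical(back$feature_id, c("a", "b", "c"))

  write_diff_table(res[0, ], f)
  expect_identical(readLines(f), header)
})
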