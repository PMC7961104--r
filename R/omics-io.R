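#' Construct an omics table
#'
#' An `omics_table` is a tibble whose first column, `feature_id`, identifies
#' the measured molecule and whose remaining columns are one numeric column
#' per sample. The omic layer (`transcript`, `protein`, `metabolite`, `lipid`
#' or `phospho_pair`) and the compartment (e.g. `"liver"`, `"muscle"`,
#' `"blood"`) are carried as attributes so tables can be passed down the
#' pipeline without loose metadata. For `phospho_pair` tables the features
#' come as (phospho, total) rows and the pairing is stored in the `pairs`
#' attribute, a tibble with columns `phospho_id` and `total_id`.
#'
#' @param values data frame with a `feature_id` column and one numeric column
#'   per sample.
#' @param layer omic layer, one of `"transcript"`, `"protein"`,
#'   `"metabolite"`, `"lipid"`, `"phospho_pair"`.
#' @param compartment free-text compartment label.
#' @param pairs for the `phospho_pair` layer, a tibble pairing phospho and
#'   total feature IDs.
#' @return a validated `omics_table`.
#' @export
omics_table <- function(values, layer, compartment, pairs = NULL) {
  layer <- match.arg(layer, LAYERS)
  tbl <- as_tibble(values)
  attr(tbl, "layer") <- layer
  attr(tbl, "compartment") <- compartment
  if (!is.null(pairs)) attr(tbl, "pairs") <- as_tibble(pairs)
  class(tbl) <- c("omics_table", class(tbl))
  validate_omics_table(tbl)
}

#' @export
print.omics_table <- function(x, ...) {
  cat(sprintf("<omics_table: %s / %s, %d features x %d samples>\n",
              table_layer(x), table_compartment(x), nrow(x), ncol(x) - 1L))
  NextMethod()
}

#' @rdname omics_table
#' @param x an `omics_table`.
#' @export
table_layer <- function(x) attr(x, "layer")

#' @rdname omics_table
#' @export
table_compartment <- function(x) attr(x, "compartment")

#' @rdname omics_table
#' @export
table_samples <- function(x) setdiff(names(x), "feature_id")

# Values as a features x samples matrix (rownames = feature IDs).
table_matrix <- function(x) {
  m <- as.matrix(x[table_samples(x)])
  rownames(m) <- x$feature_id
  m
}

validate_omics_table <- function(x, design = NULL) {
  assert_that(names(x)[1] == "feature_id", "first column must be 'feature_id'")
  dup <- unique(x$feature_id[duplicated(x$feature_id)])
  assert_that(length(dup) == 0,
              paste0("duplicate feature ID(s): ", paste(dup, collapse = ", ")))
  m <- table_matrix(x)
  assert_that(all(is.finite(m) | is.na(m)), "non-finite abundance values")
  assert_that(all(m >= 0, na.rm = TRUE), "negative abundance values")
  if (identical(table_layer(x), "transcript")) {
    bad <- which(m != floor(m), arr.ind = TRUE)
    assert_that(nrow(bad) == 0,
                paste0("transcript counts must be integers; feature '",
                       rownames(m)[bad[1, 1]], "' has value ",
                       m[bad[1, , drop = FALSE]]))
  }
  if (identical(table_layer(x), "phospho_pair")) {
    pairs <- attr(x, "pairs")
    assert_that(!is.null(pairs), "phospho_pair table needs a 'pairs' attribute")
    missing <- setdiff(c(pairs$phospho_id, pairs$total_id), x$feature_id)
    assert_that(length(missing) == 0,
                paste0("pair member(s) not measured: ",
                       paste(missing, collapse = ", ")))
  }
  if (!is.null(design)) {
    unknown <- setdiff(table_samples(x), design$sample_id)
    assert_that(length(unknown) == 0,
                paste0("sample(s) absent from design: ",
                       paste(unknown, collapse = ", ")))
  }
  x
}

#' Read a delimited omics matrix
#'
#' Expects tab-separated text with a header row of sample IDs and a first
#' column of feature IDs; `NA` marks missing values. IDs are whitespace
#' trimmed; numeric parsing is strict and reports the offending row and
#' column. Transcript tables must contain non-negative integers.
#'
#' @param path file path.
#' @inheritParams omics_table
#' @param pairs optional pairing tibble for `phospho_pair` layers.
#' @return an `omics_table`.
#' @export
read_omics_table <- function(path, layer, compartment, pairs = NULL) {
  raw <- readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                         progress = FALSE)
  names(raw) <- trimws(names(raw))
  names(raw)[1] <- "feature_id"
  raw$feature_id <- trimws(raw$feature_id)
  for (j in setdiff(names(raw), "feature_id")) {
    cell <- trimws(raw[[j]])
    num <- suppressWarnings(as.numeric(cell))
    bad <- which(is.na(num) & !is.na(cell) & cell != "NA")
    assert_that(length(bad) == 0,
                sprintf("non-numeric value '%s' at row %d, column '%s'",
                        cell[bad[1]], bad[1], j))
    raw[[j]] <- num
  }
  omics_table(raw, layer = layer, compartment = compartment, pairs = pairs)
}

#' Write an omics table as TSV
#' @param x an `omics_table`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_omics_table <- function(x, path) {
  readr::write_tsv(as_tibble(as.data.frame(x)), path, na = "NA")
  invisible(path)
}

#' Read a sample design table
#'
#' Two-column TSV `sample_id`, `condition` with conditions `control`/`case`
#' (aliases `WT` -> control, `ob/ob`, `obob`, `case` -> case accepted). A
#' replicate index per condition is added.
#'
#' @param path file path.
#' @return tibble with columns `sample_id`, `condition`, `replicate`.
#' @export
read_sample_design <- function(path) {
  raw <- readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                         progress = FALSE)
  names(raw)[1:2] <- c("sample_id", "condition")
  sample_design(trimws(raw$sample_id), trimws(raw$condition))
}

#' @rdname read_sample_design
#' @param sample_id character vector of sample IDs.
#' @param condition character vector of condition labels, parallel to
#'   `sample_id`.
#' @export
sample_design <- function(sample_id, condition) {
  alias <- c(control = "control", wt = "control",
             case = "case", `ob/ob` = "case", obob = "case")
  cond <- alias[tolower(condition)]
  bad <- unique(condition[is.na(cond)])
  assert_that(length(bad) == 0,
              paste0("unknown condition token(s): ", paste(bad, collapse = ", ")))
  dup <- unique(sample_id[duplicated(sample_id)])
  assert_that(length(dup) == 0,
              paste0("duplicate sample ID(s): ", paste(dup, collapse = ", ")))
  out <- tibble(sample_id = sample_id, condition = unname(cond)) |>
    group_by(.data$condition) |>
    mutate(replicate = row_number()) |>
    ungroup()
  assert_that(all(c("control", "case") %in% out$condition),
              "design must contain both a control and a case group")
  assert_that(all(table(out$condition) >= 2),
              "need at least 2 replicates per condition")
  out
}

design_split <- function(design) {
  list(control = design$sample_id[design$condition == "control"],
       case = design$sample_id[design$condition == "case"])
}

#' Write a differential-result table
#'
#' Columns are written in the fixed order `feature_id`, `layer`,
#' `compartment`, `log2fc`, `stat`, `df`, `p`, `q`, `class`, sorted stably by
#' `q` then `feature_id`; missing values render as `NA`.
#'
#' @param results a diff-result tibble (see [diff_molecules()]).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_diff_table <- function(results, path) {
  cols <- c("feature_id", "layer", "compartment", "log2fc", "stat", "df",
            "p", "q", "class")
  out <- as_tibble(results)
  for (c in setdiff(cols, names(out))) out[[c]] <- NA
  out <- out[order(out$q, out$feature_id), cols]
  readr::write_tsv(out, path, na = "NA")
  invisible(path)
}

#' @rdname write_diff_table
#' @export
read_diff_table <- function(path) {
  readr::read_tsv(path, col_types = readr::cols(
    feature_id = "c", layer = "c", compartment = "c", log2fc = "d",
    stat = "d", df = "d", p = "d", q = "d", class = "c"), progress = FALSE)
}
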