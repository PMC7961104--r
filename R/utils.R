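# Internal helpers shared across modules.

LAYERS <- c("transcript", "protein", "metabolite", "lipid", "phospho_pair")

# Ordered layers of the assembled network, top to bottom.
NETWORK_LAYERS <- c("insulin_signal", "tf", "enzyme_mrna", "enzyme_protein",
                    "reaction", "metabolite")

EDGE_TYPES <- c("kinase_tf", "tf_gene", "gene_protein", "enzyme_reaction",
                "allosteric", "mass_action")

`%nin%` <- function(x, table) !x %in% table

assert_that <- function(ok, msg) {
  if (!isTRUE(ok)) abort(msg, class = "transomix_validation_error")
}

config_error <- function(msg) abort(msg, class = "transomix_config_error")

# Round half away from zero (the convention used for printed percentages;
# base round() is banker's rounding).
round_half_up <- function(x, digits = 0) {
  scale <- 10^digits
  sign(x) * floor(abs(x) * scale + 0.5) / scale
}

# One RNG seed per named stage, derived from a master seed so stages are
# reproducible independently of evaluation order. Kept below 2^31.
derive_seed <- function(seed, stage) {
  offs <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  (as.integer(seed) * 1009L + as.integer(offs %% 99991L)) %% 2147483647L
}

with_seed <- function(seed, code) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) runif(1)
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  force(code)
}

split_ids <- function(x) {
  out <- strsplit(ifelse(is.na(x) | x == "", "", x), ",", fixed = TRUE)
  lapply(out, function(v) trimws(v[nzchar(trimws(v))]))
}

join_ids <- function(x) vapply(x, paste, character(1), collapse = ",")

node_key <- function(layer, id) paste(layer, id, sep = ":")
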