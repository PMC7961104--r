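#' Welch's two-sample t test
#'
#' Unequal-variance t statistic
#' \eqn{t = (\bar x - \bar y)/\sqrt{s_x^2/n_x + s_y^2/n_y}} with
#' Welch-Satterthwaite degrees of freedom and a two-tailed p value. When both
#' groups have zero variance and equal means the statistic is 0 and p = 1 by
#' convention (the case stats::t.test() refuses).
#'
#' @param x,y numeric replicate vectors, each of length >= 2.
#' @return list with `stat`, `df`, `p`.
#' @export
welch_t_test <- function(x, y) {
  assert_that(length(x) >= 2 && length(y) >= 2,
              "need at least 2 replicates per group")
  assert_that(all(is.finite(x)) && all(is.finite(y)), "non-finite values")
  vx <- stats::var(x); vy <- stats::var(y)
  if (vx == 0 && vy == 0) {
    if (mean(x) == mean(y)) return(list(stat = 0, df = NA_real_, p = 1))
    return(list(stat = sign(mean(y) - mean(x)) * Inf, df = NA_real_, p = 0))
  }
  se2 <- vx / length(x) + vy / length(y)
  stat <- (mean(x) - mean(y)) / sqrt(se2)
  df <- se2^2 / (vx^2 / (length(x)^2 * (length(x) - 1)) +
                 vy^2 / (length(y)^2 * (length(y) - 1)))
  list(stat = stat, df = df, p = 2 * pt(-abs(stat), df))
}

#' Negative-binomial exact test for count data
#'
#' Per-gene two-sided exact tests for a two-group RNA-seq comparison, run
#' through edgeR's classic pipeline with default parameters: effective
#' library sizes by TMM (or raw library sizes), common then tagwise
#' dispersion estimation, and the conditional exact test.
#'
#' @param counts integer matrix, genes x samples.
#' @param design a sample design (see [sample_design()]); columns of `counts`
#'   must be named by `design$sample_id`.
#' @param norm `"tmm"` or `"libsize"`.
#' @return tibble with `feature_id`, `log2fc` (case vs control, edgeR's
#'   logFC), `p`, and the common `dispersion` as an attribute.
#' @export
nb_exact_test <- function(counts, design, norm = c("tmm", "libsize")) {
  norm <- match.arg(norm)
  assert_that(all(counts == floor(counts)), "counts must be integers")
  counts <- counts[, design$sample_id, drop = FALSE]
  group <- factor(design$condition, levels = c("control", "case"))
  y <- edgeR::DGEList(counts = counts, group = group)
  y <- edgeR::calcNormFactors(y, method = if (norm == "tmm") "TMM" else "none")
  y <- edgeR::estimateCommonDisp(y)
  y <- edgeR::estimateTagwiseDisp(y)
  et <- edgeR::exactTest(y, pair = c("control", "case"))
  out <- tibble(feature_id = rownames(et$table),
                log2fc = et$table$logFC,
                p = et$table$PValue)
  # all-zero genes carry no information; p = 1 by convention
  out$p[rowSums(counts) == 0] <- 1
  attr(out, "dispersion") <- y$common.dispersion
  out
}

#' Storey q-values
#'
#' Estimates the null proportion \eqn{\pi_0} from the flat right tail of the
#' p-value distribution, \eqn{\hat\pi_0(\lambda) = \#\{p > \lambda\} /
#' (m(1-\lambda))}, then converts p values to q values by the step-up
#' minimum over tails, \eqn{q_{(i)} = \min_{j \ge i} \hat\pi_0 m p_{(j)}/j}.
#' In `smoother` mode a cubic smoothing spline is fitted to
#' \eqn{\hat\pi_0(\lambda)} over the lambda grid and evaluated at the
#' largest lambda; `fixed` mode uses the single `fixed_lambda`. Small input
#' vectors (m below `small_m`) fall back to fixed mode, where the spline is
#' unstable. The estimate is clamped to (0, 1].
#'
#' @param p numeric vector of p values in \[0, 1\].
#' @param lambda lambda grid for \eqn{\pi_0} estimation.
#' @param pi0_method `"smoother"` or `"fixed"`.
#' @param fixed_lambda lambda used in fixed mode.
#' @param small_m below this many p values the smoother falls back to fixed
#'   mode.
#' @param pi0 optionally force \eqn{\pi_0} (e.g. `pi0 = 1` reproduces
#'   Benjamini-Hochberg exactly).
#' @return q values, parallel to `p`; the `pi0` estimate as an attribute.
#' @export
storey_qvalues <- function(p, lambda = seq(0.05, 0.95, by = 0.05),
                           pi0_method = c("smoother", "fixed"),
                           fixed_lambda = 0.5, small_m = 100, pi0 = NULL) {
  pi0_method <- match.arg(pi0_method)
  if (length(p) == 0) return(numeric(0))
  assert_that(all(p >= 0 & p <= 1), "p values must lie in [0, 1]")
  m <- length(p)
  if (is.null(pi0)) {
    if (pi0_method == "smoother" && m < small_m) pi0_method <- "fixed"
    if (pi0_method == "fixed") {
      pi0 <- sum(p > fixed_lambda) / (m * (1 - fixed_lambda))
    } else {
      pi0_l <- vapply(lambda, function(l) sum(p > l) / (m * (1 - l)), 0)
      fit <- smooth.spline(lambda, pi0_l, df = 3)
      pi0 <- predict(fit, x = max(lambda))$y
    }
    pi0 <- min(max(pi0, 1 / m), 1)
  }
  q <- step_up(p, pi0)
  attr(q, "pi0") <- pi0
  q
}

# min-over-tails step-up on pi0*m*p/rank; ties broken stably by order().
step_up <- function(p, pi0) {
  m <- length(p)
  o <- order(p)
  raw <- pi0 * m * p[o] / seq_len(m)
  q_sorted <- rev(cummin(rev(pmin(raw, 1))))
  q <- numeric(m)
  q[o] <- q_sorted
  q
}

#' Benjamini-Hochberg q-values
#'
#' The step-up formula \eqn{q_{(i)} = \min_{j \ge i} m p_{(j)}/j}, capped at
#' 1; identical to [storey_qvalues()] with \eqn{\pi_0 = 1}.
#'
#' @inheritParams storey_qvalues
#' @return q values, parallel to `p`.
#' @export
bh_qvalues <- function(p) {
  if (length(p) == 0) return(numeric(0))
  assert_that(all(p >= 0 & p <= 1), "p values must lie in [0, 1]")
  p.adjust(p, method = "BH")
}

#' Log2 fold change of group means
#'
#' \eqn{\log_2((\bar y_{case} + \epsilon)/(\bar x_{control} + \epsilon))},
#' i.e. the fold change of averaged replicate values, case over control.
#'
#' @param x control replicate values (non-negative).
#' @param y case replicate values (non-negative).
#' @param pseudocount stabilising offset \eqn{\epsilon} (default 0).
#' @return a single log2 fold change.
#' @export
log2_fold_change <- function(x, y, pseudocount = 0) {
  assert_that(all(x >= 0) && all(y >= 0), "abundances must be non-negative")
  log2((mean(y) + pseudocount) / (mean(x) + pseudocount))
}

#' Classify features as increased / decreased / unchanged
#'
#' A feature is `increased` when q < `q_threshold` (strict) and log2fc > 0,
#' `decreased` when q < `q_threshold` and log2fc < 0, otherwise `unchanged`.
#'
#' @param results tibble with at least `q` and `log2fc` columns.
#' @param q_threshold significance threshold on the q value (default 0.1).
#' @return `results` with a `class` column.
#' @export
classify_features <- function(results, q_threshold = 0.1) {
  results |>
    mutate(class = dplyr::case_when(
      .data$q < q_threshold & .data$log2fc > 0 ~ "increased",
      .data$q < q_threshold & .data$log2fc < 0 ~ "decreased",
      TRUE ~ "unchanged"
    ))
}

# epsilon for the log transform: half the smallest nonzero value in the table
half_min_nonzero <- function(m) {
  nz <- m[m > 0 & is.finite(m)]
  if (length(nz) == 0) return(0.5)
  min(nz) / 2
}

#' Differential molecules for one omic layer
#'
#' Stage 1 of the pipeline: per-feature two-condition tests, FDR-adjusted
#' q values and increased/decreased/unchanged classification. Transcript
#' counts go through the negative-binomial exact test ([nb_exact_test()]);
#' abundance layers through Welch's t test, by default on
#' log2(abundance + eps) with eps half the smallest nonzero value of the
#' table (raw scale selectable). Fold changes are always ratios of raw
#' group means, case over control.
#'
#' @param table an `omics_table`.
#' @param design a sample design covering the table's samples.
#' @param method `"welch"` or `"nb"`; default picks `"nb"` for transcript
#'   layers and `"welch"` otherwise.
#' @param q_method `"storey"` or `"bh"`.
#' @param q_threshold classification threshold (default 0.1).
#' @param log_transform run Welch tests on log2(abundance + eps)?
#' @param pseudocount fold-change offset (default 0).
#' @return tibble with `feature_id`, `layer`, `compartment`, `log2fc`,
#'   `stat`, `df`, `p`, `q`, `class`.
#' @export
diff_molecules <- function(table, design,
                           method = NULL,
                           q_method = c("storey", "bh"),
                           q_threshold = 0.1,
                           log_transform = TRUE,
                           pseudocount = 0) {
  q_method <- match.arg(q_method)
  layer <- table_layer(table)
  if (is.null(method)) method <- if (layer == "transcript") "nb" else "welch"
  validate_omics_table(table, design)
  m <- table_matrix(table)
  grp <- design_split(design)
  if (method == "nb") {
    res <- nb_exact_test(m, design)
    out <- tibble(feature_id = res$feature_id,
                  log2fc = res$log2fc,
                  stat = NA_real_, df = NA_real_, p = res$p)
  } else {
    tm <- m
    if (log_transform) tm <- log2(m + half_min_nonzero(m))
    tests <- purrr::map(seq_len(nrow(m)), function(i)
      welch_t_test(tm[i, grp$control], tm[i, grp$case]))
    out <- tibble(
      feature_id = rownames(m),
      log2fc = vapply(seq_len(nrow(m)), function(i)
        log2_fold_change(m[i, grp$control], m[i, grp$case], pseudocount), 0),
      stat = map_dbl(tests, "stat"),
      df = map_dbl(tests, "df"),
      p = map_dbl(tests, "p"))
  }
  out$q <- if (q_method == "storey") as.numeric(storey_qvalues(out$p))
           else bh_qvalues(out$p)
  out |>
    mutate(layer = layer, compartment = table_compartment(table),
           .after = "feature_id") |>
    classify_features(q_threshold)
}

#' Differentially phosphorylated proteins from phospho/total pairs
#'
#' For each (phospho, total) western-blot pair the per-replicate ratio
#' phospho/total is formed, conditions are compared by Welch's t test on the
#' ratios, q values computed (Storey with small-m fallback) and pairs
#' classified at q < `q_threshold` as the differentially phosphorylated
#' proteins (DPPs). Pairs whose total signal is zero in any sample are
#' excluded with a warning.
#'
#' @param pairs_table an `omics_table` of layer `phospho_pair`.
#' @param design sample design.
#' @param q_threshold classification threshold (default 0.1).
#' @return a diff-result tibble keyed by the phospho feature ID.
#' @export
phospho_ratio_test <- function(pairs_table, design, q_threshold = 0.1) {
  assert_that(identical(table_layer(pairs_table), "phospho_pair"),
              "pairs_table must be a phospho_pair omics_table")
  validate_omics_table(pairs_table, design)
  pairs <- attr(pairs_table, "pairs")
  m <- table_matrix(pairs_table)
  grp <- design_split(design)
  ok <- map_lgl(pairs$total_id, ~ all(m[.x, ] > 0))
  if (any(!ok)) {
    warn(paste0("excluding pair(s) with zero total signal: ",
                paste(pairs$phospho_id[!ok], collapse = ", ")))
    pairs <- pairs[ok, , drop = FALSE]
  }
  if (nrow(pairs) == 0) {
    return(classify_features(tibble(
      feature_id = character(), layer = character(),
      compartment = character(), log2fc = numeric(), stat = numeric(),
      df = numeric(), p = numeric(), q = numeric()), q_threshold))
  }
  rows <- pmap(pairs, function(phospho_id, total_id) {
    ratio <- m[phospho_id, ] / m[total_id, ]
    t <- welch_t_test(ratio[grp$control], ratio[grp$case])
    tibble(feature_id = phospho_id,
           log2fc = log2_fold_change(ratio[grp$control], ratio[grp$case]),
           stat = t$stat, df = t$df, p = t$p)
  })
  out <- bind_rows(rows)
  out$q <- if (nrow(out)) as.numeric(storey_qvalues(out$p)) else numeric(0)
  out |>
    mutate(layer = "phospho_pair",
           compartment = table_compartment(pairs_table),
           .after = "feature_id") |>
    classify_features(q_threshold)
}
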