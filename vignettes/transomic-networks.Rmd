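---
title: "Building trans-omic networks of differentially regulated metabolic reactions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Building trans-omic networks of differentially regulated metabolic reactions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(transomix)
library(dplyr)
```

# The problem

Systemic metabolism is maintained by metabolic cycles that span organs:
skeletal muscle exports alanine and lactate, the liver turns them back into
glucose (the glucose-alanine and Cori cycles), and in fasting the liver
exports ketone bodies that other organs burn. Obesity perturbs these cycles,
but each omic layer — transcripts, proteins, metabolites, lipids,
phosphorylation states of signalling proteins — sees only part of the
perturbation. `transomix` implements a pipeline that integrates all of these
layers per organ into a single six-layer network of *differentially
regulated metabolic reactions* between two conditions (a control group and a
case group, such as lean versus obese mice), and then compares metabolite
changes across organs and blood.

The pipeline has four stages:

1. **Differential molecules.** Per layer and organ, each feature is tested
   for a two-condition difference and classified `increased`, `decreased`
   or `unchanged` at q < 0.1.
2. **Differential regulations.** Knowledge-base tables convert
   differential molecules into *signed* edges: kinase to TF, TF to target
   gene, gene to encoded protein, metabolic enzyme to catalysed reaction,
   allosteric metabolite to reaction, substrate/product to reaction.
3. **Network assembly.** Edges and molecules that reach a metabolic
   reaction are stacked into six layers (Insulin Signal, TF, Enzyme mRNA,
   Enzyme Protein, Metabolic Reaction, Metabolite) and each reaction is
   classified `activated`, `inhibited` or `controversial`.
4. **Inter-organ comparison.** Differential metabolites are intersected
   across organs and blood, their fold changes correlated, and the built-in
   cycle definitions rendered as structured verdicts.

# Statistical procedures

**Tests per layer.** Transcript counts are tested with the classic
negative-binomial exact-test pipeline of edgeR with default parameters (TMM
effective library sizes, common then tagwise dispersion, conditional exact
test). Proteins, polar metabolites and lipids are tested with Welch's
two-tailed unequal-variance t test; phospho/total western-blot pairs are
reduced to per-replicate ratios first, so that a shift in total protein
alone never looks like a phosphorylation change.

**Scale of the Welch test.** The published legends do not state whether
abundance tests ran on the raw or the log scale. We test
`log2(abundance + eps)` with `eps` set to half the smallest nonzero value of
the table, because mass-spectrometry abundances are approximately
log-normal and the log transform stabilises their variance; a raw-scale
mode is available (`log_transform = FALSE`). Fold changes are always ratios
of raw group means (case over control) — the convention of reporting the
fold change of averaged replicate values rather than averaged per-pair fold
changes.

**False-discovery control.** Transcripts, proteins and polar metabolites
use Storey's q-values: the null proportion is estimated from the flat right
tail of the p-value histogram, pi0(lambda) = #{p > lambda} / (m (1 -
lambda)), smoothed over lambda in 0.05..0.95 with a cubic spline and
evaluated at the largest lambda, then plugged into the step-up minimum over
tails. Below m = 100 p-values the spline is unreliable and the estimator
falls back to the single-lambda form at lambda = 0.5 (this small-m fallback
is also what the phospho-ratio layer, with its ~14 pairs, effectively
uses). Lipids use plain Benjamini-Hochberg, which equals the Storey formula
with pi0 fixed at 1 — with only three replicates per group the lipid layer
has too little information to estimate pi0. The classification threshold is
a *strict* q < 0.1.

**TF inference.** Motif enrichment is a one-tailed hypergeometric test of a
motif's target set against each direction of DEGs separately (increased and
decreased sets are biologically distinct regulons), with BH correction
across motifs and the organ's detected transcriptome as the background
universe. A TF whose motif is enriched and whose own gene is a DEG is a
DETF, with activity equal to its expression change. A phospho-TF among the
differentially phosphorylated proteins whose motif is enriched is a DPTF;
its activity combines the phospho change with the annotated effect of the
phosphorylation, so an increased inactivating phosphorylation (the
Foxo1/nuclear-export case) means *decreased* activity.

**The sign algebra.** Every edge sign is `combine_signs(change, mode)`:
activating iff (increased, activation) or (decreased, inhibition). This
single pure function is used by every edge constructor and re-applied by
the validation layer, so a sign bug cannot hide in one edge type.

# Design choices where the method was open

* **Substrate/product signs.** Only allosteric metabolite edges carry
  published signs in the network figures; whether substrate/product
  (mass-action) edges should be signed is not stated. The default treats
  mass-action edges as unsigned context (they are emitted, but do not enter
  reaction classification); `mass_action_signed = TRUE` turns on the
  natural convention — substrate accumulation activates, product
  accumulation inhibits — and `treat_reversible = "both_sides"`
  additionally treats products of reversible reactions as substrates of the
  reverse direction.
* **Within-layer conflicts.** "Controversial" is defined strictly as
  opposing input *across* the Enzyme Protein and Metabolite layers. A
  reaction with opposing input *within* one layer gets its own class,
  `mixed_within_layer`, rather than being silently merged; `fold_mixed =
  TRUE` reproduces the merged behaviour.
* **TF regulation is activation-only.** The motif tables carry no
  repressor annotation, so a TF-target edge is emitted only when the target
  DEG moves with the TF's activity. Discordant gene-protein pairs likewise
  produce no edge (only "consistent changes" count) but are returned in a
  side report for auditing.
* **DRTF-pathway association.** The procedure is a one-tailed Fisher's
  exact test called significant at q < 0.01, with the multiple-testing
  correction left unnamed in the source legends; we use BH across all
  (DRTF, pathway) pairs per organ. The universe is the set of
  differentially regulated reactions in that organ's network, and a DRTF's
  reaction set is everything reachable through a TF -> gene -> protein ->
  reaction chain of differential regulations.
* **Cycle verdicts.** The published interpretation of cycle dysfunction is
  narrative; `cycle_report()` formalises it: a carried metabolite is an
  `imbalance` when its blood change matches the releasing organ's pool and
  opposes the uptaking organ's pool, `insufficient_data` when any member
  (metabolite, enzyme, transporter) of a leg carrying it went unmeasured,
  and `consistent` otherwise. This is an interpretation layer on top of the
  statistics, not a published statistic.

# The synthetic-study generator

Real studies of this design cannot be re-measured at a desk, so every stage
is tested against `generate_study()`, which emulates the study conditions:

* replicate counts 11 control / 12 case for the transcriptome, 5/5 for
  proteome, metabolome and phospho blots, 3/3 for the lipidome;
* negative-binomial counts with variance mu + phi mu^2 (default phi = 0.1,
  a typical RNA-seq dispersion) around log-normal baselines, with library
  sizes varying +/-30%;
* log-normal abundances with 20% CV (15% for western-blot signals);
* planted effects |log2FC| ~ Uniform(0.5, 2) on 20% of features per layer;
* gene-protein coupling probabilities 0.6 (increased) / 0.4 (decreased),
  mirroring the reported shares of DEPs explained by DEGs;
* planted active TFs whose motif targets are enriched among their own
  direction of planted DEGs at odds ratio 8;
* a blood compartment carrying only metabolites whose fold changes
  correlate with the first organ's at Pearson r = 0.4.

Every random draw derives from one master seed, so a bundle is exactly
reproducible. The generator also emits the *expected* network, computed at
generation time by `enumerate_expected_network()` — a deliberately
independent brute-force enumeration (plain loops and an explicit 2x2 sign
table, no shared code with the pipeline) — so network assembly can be
checked for exact node/edge/classification agreement.

What the generator does **not** emulate: mass-spectrometry missingness,
batch effects, correlated features within pathways, and isotope-tracer
dynamics. Passing tests therefore demonstrate the correctness of the
statistical and set logic under the stated generative model, not
performance on real measurements.

# Numerical conventions

* Percentages reported in summaries are rounded half-away-from-zero, the
  convention of the printed values they mirror.
* Classification thresholds are strict inequalities (q = 0.1 exactly is
  `unchanged`).
* Ties in p are handled by the stable step-up on sorted values; q vectors
  are monotone in p and permutation-invariant up to feature order.
* Welch's test with zero variance in both groups returns p = 1 for equal
  means (no evidence) and p = 0 for unequal means.
* All-zero count genes get p = 1.
* Pathways with no in-network reactions are excluded from pathway
  percentages and listed in an attribute; motifs with no background
  targets, allosteric entries with unknown enzymes and phospho pairs with
  zero total signal are skipped with warnings, never silently dropped.

# Problem sizes used in the checks

The shipped tests and the acceptance script run the generator at moderate
sizes chosen to exercise every code path with comfortable statistical
power: null calibrations at 2,000 features, false-discovery checks over 20
simulations of 400 proteins, TF recovery over 20 simulations of 800 genes
and 20 TFs, and network-oracle comparisons over dozens of randomized
studies with 10-50 reactions. These sizes are the package's own test
design; the functions themselves are vectorised and handle
transcriptome-scale inputs.

# Worked example

```{r example}
cfg <- sim_config(seed = 1)
study <- generate_study(cfg)
res <- suppressWarnings(run_pipeline(study, cycles = built_in_cycles()))
glance(res$networks$liver)
res$stats$liver$controversial$percent
head(tidy(res$networks$liver))
res$interorgan$correlations
```

# Known limitations

* The negative-binomial route relies on edgeR's classic exact test; other
  DE engines (limma-voom, quasi-likelihood GLMs) are out of scope.
* Phosphosite-level regulation of enzymes, epigenomic and RNA-mediated
  regulation are not modelled; the Insulin Signal layer enters only through
  the curated kinase-TF table.
* Reaction classification weighs each regulator equally; no quantitative
  regulation strengths or kinetic rate laws are attempted.
* Cycle verdicts depend on the curated cycle membership lists; they are
  editable YAML fixtures, not discovered from data.
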