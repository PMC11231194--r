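---
title: "Screening multi-herb formulas with compound-target-pathogenic-gene networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Screening multi-herb formulas with compound-target-pathogenic-gene networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ctpflow)
```

Traditional multi-herb prescriptions contain hundreds to thousands of
chemical constituents, of which only a handful are plausibly absorbed,
reach relevant protein targets, and act on the genes driving a disease.
`ctpflow` implements a network-pharmacology screen that narrows a formula's
compound list down to a minimal combination explaining most of the predicted
action on a disease gene set. This vignette documents the model, its
assumptions, the tunable parameters, and the design choices made where the
underlying procedure is genuinely open.

## Inputs and their meaning

The pipeline consumes generic tabular equivalents of the usual database
exports: a compound property table (one row per compound-herb pair with the
nine screenable properties), a compound-target edge list (the union of
target-prediction tools, deduplicated), a pathogenic gene list, a PPI edge
list, gene sets in GMT format, and optionally a genes-by-samples log2
expression matrix with case/control labels or a precomputed
differential-expression table. One gene namespace is assumed per run;
identifiers are case-normalized once at load and no cross-database ID
mapping is attempted — mapping is a separate concern best done upstream.
Compound identity across herbs is keyed on `compound_id`, not on names,
since the same constituent commonly appears under several herbs.

## Compound screening

A compound is retained iff it fulfils all nine criteria: MW &le; 500 Da,
nHD &le; 5, nHA &le; 10, logP &le; 5, nRot &le; 10 (the extended rule of
five), OB &ge; 30%, Caco-2 &ge; 0.4, TPSA &le; 60 &#8491;&sup2;, and no
hepatotoxicity. Comparisons are inclusive at the boundary, matching how the
criteria are conventionally written. A missing property value cannot be
"fulfilled", so it conservatively fails the compound, with a
`missing:<field>` violation and a per-field counter so heavy missingness is
visible. The Caco-2 column is used on whatever scale the upstream predictor
supplies; the threshold applies to the numeric value as-is. Rules are plain
data (`default_rules()`), so other prescriptions or stricter panels can
swap thresholds without code changes; relaxing any single threshold can only
grow the pass set, a monotonicity property the tests exercise.

## The C-T-P network

The protein node set is the union of predicted targets *T* and pathogenic
genes *P*; PPI edges are kept only when **both** endpoints are protein nodes
(the network describes relations among these node classes only — the exact
restriction used originally is unstated, so this choice is documented and
tested for idempotence). PPIs are treated as undirected and unweighted, and
self-loops are dropped. Genes in *T &cap; P* are the essential common
proteins (ECPs): targets that are themselves disease genes. Isolated
pathogenic genes remain as nodes; they simply receive zero intensity later.

## Multi-objective target scoring

The goal of optimization is to keep target genes that are simultaneously
strongly associated with compounds, strongly associated with pathogenic
genes, and dysregulated in disease. The original multi-objective model is
described only in a prior report that is not reproduced here; `ctpflow`
therefore implements a transparent scalarization of the three stated goals
and does **not** claim fidelity to the original algorithm:

* `o_compound` — sum of incident compound-target prediction scores (edge
  count when scores are absent), min-max normalized over targets;
* `o_pathogenic` — number of pathogenic PPI neighbors, plus one when the
  gene is itself an ECP (self-association is the strongest possible
  pathogenic link), min-max normalized;
* `o_dysreg` — |log2FC| from the DE table, min-max normalized over the
  targets present; genes absent from the table score 0.

S&prime;<sub>MOO</sub> is the weighted mean (equal weights by default, so it
stays in [0, 1]). A constant objective is degenerate under min-max (0/0) and
maps to all zeros with a logged message rather than propagating NaN.

Retention keeps targets scoring at or above the `(1 - keep_quantile)`
sample quantile, ties included, which makes the retained set monotone in
`keep_quantile` and deterministic without arbitrary ordering. The default
`keep_quantile = 0.5` keeps the top half — the fraction retained originally
is not recoverable, so this is an explicit, configurable choice. All
compounds and all pathogenic genes stay in the node set; compound-target
edges are restricted to retained targets, and PPI edges to those touching a
retained target or an ECP. Whether nodes, ct-edges or pp-edges were pruned
first in the original procedure is unstated; this retention rule is the
package's documented reading.

### Centrality baselines and model comparison

Degree, closeness and betweenness baselines score targets on the
protein-protein subgraph (compound nodes would distort shortest paths;
degree additionally counts compound-target edges) and share the retention
rule. `compare_models()` evaluates each model's **retained target set** —
the genes the model actually ranked — on five aspects: ECP coverage,
overlap of its top-100 enriched pathways and top-1000 enriched GO biological
processes with references enriched from the ECP set, average regulating
intensity (mean Pearson correlation over retained PPI edges, computed over
all samples since no restriction is stated; pairs lacking expression are
skipped and counted), and cumulative |log2FC| over retained ECPs. Comparing
retained target sets is a deliberate choice: under the retention rule above
every model keeps all pathogenic genes, so comparing whole node sets would
make the ECP-based metrics identical across models and the comparison
uninformative.

## Interaction-intensity flow

With scores in hand, intensity flows from targets onto pathogenic genes:

* *k* a retained target and pathogenic (ECP of the optimized network):
  Intensity<sub>k</sub> = S&prime;<sub>MOO</sub>(k);
* *k* pathogenic but not a retained target: the arithmetic mean of
  S&prime;<sub>MOO</sub> over the retained targets sharing a PPI edge with
  *k*;
* no retained-target interactions: 0.

An ECP whose target was pruned by retention is treated by the second branch
— within the optimized network it is no longer a target. The published
equations for this statistic are typographically garbled in the source
material; the two-branch reading above is the only self-consistent one and
is what the package implements and tests (to 1e-12 on hand-built networks).

A compound's correlated pathogenic set C<sub>i</sub> is not operationalized
in the original description; `ctpflow` defines it as the pathogenic genes
that are direct retained targets of the compound plus those one PPI hop from
any of its retained targets — mirroring the two branches of the gene
equation and keeping the flow local and testable. The compound intensity is
the sum of gene intensities over C<sub>i</sub>.

**Combination selection.** The intensity of a compound set is the sum over
the **union** of the members' C<sub>i</sub> (union semantics are forced:
with double counting the all-compound total could exceed "the intensity of
all compounds", making a 90% threshold ill-defined). For each size *m* the
optimal combination maximizes this union value; scanning *m* = 1, 2, ... and
stopping at the first optimal combination reaching `threshold` (default
0.90, inclusive — "reached") times the total yields the minimal qualifying
combination. Exhaustive enumeration over a realistic compound count is
infeasible, so the default solver is the standard greedy maximum-coverage
approximation (marginal-gain steps; ties broken by gain, then compound
intensity descending, then id ascending for determinism), with the exact
solver available up to `exact_limit` (default 15) compounds. The test suite
uses the exact solver as the oracle on 100 random instances; the union
value is monotone and submodular, so greedy also carries the usual
(1 &minus; 1/e) coverage guarantee per size.

**Pathway intensity.** Pathway *p* scores
&Sigma;<sub>k&isin;p&cap;P</sub> Intensity<sub>k</sub>/n<sub>k</sub>, where
n<sub>k</sub> is the number of pathways in the collection containing *k*;
a gene thus distributes exactly its own intensity across its pathways, and
the total pathway intensity equals the total intensity of pathway-annotated
pathogenic genes (conservation, asserted to 1e-9 in tests). Pathways are
ranked descending; the top 20 are reported by default.

## Enrichment and differential expression

Over-representation uses the upper-tail hypergeometric probability
P[X &ge; k] (the observed overlap included, the standard convention), with
Benjamini-Hochberg FDR across the tested terms and significance at
FDR &le; 0.05. Term sizes are counted **within the universe** (the
documented reading of a "fewer than 10 genes" filter), and the default
universe is all genes in the annotation collection, overridable. Top-N term
lists keep ties at the cut, so reference lists are reproducible regardless
of input order.

`simple_de()` replaces moderated-statistics machinery with a transparent
Welch t-test on log2-scale values: logFC = mean(case) &minus; mean(control),
BH FDR, and the conventional |logFC| &gt; 1, FDR &lt; 0.05 flag.
Empirical-Bayes moderation matters most for very small sample counts; for
the synthetic studies here (10 vs 10) the Welch test is essentially fully
powered at the planted effect size, and real studies can supply a
precomputed DE table (`read_de_table()`) instead, which the pipeline uses
verbatim.

## The synthetic-data generator

`generate_synthetic()` emulates the full input bundle with planted ground
truth. Generation is **label-first**: pass/fail labels, the ECP set and the
DE gene set are drawn before the observable values are sampled conditional
on them. A planted passer's properties are drawn inside all nine admissible
ranges; a planted failer receives one to three violations drawn strictly
beyond the thresholds, so screening recovery is exact rather than
probabilistic. Defaults mirror the study conditions the pipeline was built
around: 8 herbs, pass fraction 0.22, ECP fraction 0.16 of the pathogenic
list, |log2FC| = 2 planted on 40% of ECPs, Gaussian noise with sd 0.5 on
the log2 scale, and 10 samples per group; network sizes (200 compounds, 150
targets, 120 pathogenic genes) are scaled down so a full pipeline run takes
seconds. The PPI layer is Erd&#337;s&ndash;R&eacute;nyi (edge probability
0.02) — the simplest null; real interactomes are scale-free and modular,
and a fifth of the targets are planted as high compound-degree "signal"
targets to give the ranking something to find. Consequently, passing tests
demonstrate correctness of the computations and recovery of planted signal
under a simple generative model; they do not certify performance on real
interactomes, real ADMET predictions, or microarray noise.

Every file the generator writes round-trips through the package readers,
and the bundle is a pure function of its config (seed included):
regenerating with the same config reproduces the files byte for byte.

## Pipeline, determinism, and problem sizes

`run_pipeline()` composes the stages under one config (R list, YAML file,
or `pipeline_config()`), writes every intermediate as a plain file plus a
JSON report and a YAML config snapshot, and aborts with a `FAILED` marker
naming the stage on error. All randomness flows from the single config
seed, so a fixed seed reproduces the report byte for byte. The exported
functions are the interface — each pipeline stage (`simulate`, `screen`,
`build-net`, `optimize`, `compare-models`, `intensity`, `select`,
`pathway-rank`, `enrich`, `run-all`) corresponds one-to-one to an exported
function, and `run_pipeline()` is the `run-all` composition; the package is
library-first and ships no shell executable.

The shipped validation workloads use deliberately modest sizes — a
1,000-compound screening table, 20 benchmark replicates of the default
study, 200 + 100 DE simulations, and 100 combination-oracle instances —
chosen so the whole suite completes in well under a minute on one core
while still estimating rates with useful precision.

## Known limitations

* The scalarized MOO model matches the *stated goals* of the original
  optimization, not its (unpublished) internals; Pareto-rank scoring and
  non-equal weights are available via `optimize_moo(weights = ...)` for
  sensitivity analysis.
* C<sub>i</sub> reachability is one PPI hop; longer diffusion is out of
  scope.
* The generator's PPI topology and property distributions are simple nulls,
  not calibrated to real databases.
* No compound identity reconciliation across source databases and no SMILES
  processing: ids are taken as supplied.
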