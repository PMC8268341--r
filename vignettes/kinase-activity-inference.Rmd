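---
title: "Inferring kinase activities from differential phosphoproteomics"
author: "phosact"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring kinase activities from differential phosphoproteomics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phosact)
```

## The problem

Protein kinases drive most signal transduction, and shifts in their
activities underlie both oncogenesis and the response to kinase inhibitors.
A kinase's activity is not measured directly by shotgun phosphoproteomics;
what is measured is the abundance of phosphorylated sites (phosphosites) on
its substrates. `phosact` infers which kinases are over- or under-active
between two biological conditions by asking whether the *known substrates*
of each kinase are concentrated near the top of a ranked list of
differentially phosphorylated sites — once in an over-expression ranking and
once in an under-expression ranking, so that activation and inhibition are
detected symmetrically.

The pipeline covers: parsing MaxQuant `Phospho (STY)Sites` tables,
filtering, normalization, imputation, per-site Welch tests, assembly of a
kinase–substrate meta-database from public resources plus sequence-based
predictions, an overlap-aware ranked enrichment, and reporting (waterfall
table/plot, network-import tables).

## Preprocessing model

**Parsing and site identity.** Each row of a MaxQuant sites table carries up
to three intensity column blocks (`___1`, `___2`, `___3`) for singly, doubly
and triply phosphorylated peptides. One record is produced per (row,
multiplicity) pair with at least one quantified intensity; zeros are read as
missing, multi-protein groups are reduced to their leading entry. Sites are
keyed as `GENE_<residue><position>[_m<k>]` (e.g. `CRKL_Y207_m1`). By
default multiplicity variants remain distinct rows because their biological
regulation can differ; a switch collapses them. Records that collapse to the
same key are summed on the linear scale, preserving total ion signal.

**Filtering.** Potential contaminants and reverse-database hits are removed,
then sites with localization probability below 0.75 (the boundary value is
kept). The threshold is the field's conventional "class I site" cutoff.

**Normalization.** Intensities are log2-transformed and quantile-normalized
across samples (classic sort/row-mean/restore). Because normalization runs
*before* imputation, missing values must be handled: ranks are computed
among each column's observed values and the reference distribution is
interpolated to each column's observed count, with ties averaged. This is
exactly the behaviour of `limma::normalizeQuantiles(ties = TRUE)`, which
`quantile_normalize()` uses.

**Missingness and imputation.** Within a condition of *n* replicates a site
is *complete* (none missing), *MAR* (exactly one missing — sporadic,
missing-at-random dropout) or *MNAR* (two or more missing — systematic,
intensity-driven absence). For triplicates this is the 1-of-3 versus
2-or-3-of-3 rule. The two mechanisms get different treatments:

* **MAR** cells are filled with their conditional expectation under a
  multivariate normal over the condition's replicates, fitted by maximum
  likelihood with an EM algorithm (initialized from rows complete in that
  condition; at most 100 iterations, tolerance 1e-6 on the observed-data
  log-likelihood; a small ridge keeps the covariance invertible, and a
  diagonal fallback is used when fewer than ~5 complete rows exist).
* **MNAR** cells are treated as left-censored and drawn independently from a
  Gaussian centred at the 0.01-quantile of the sample's observed
  distribution (the MinProb convention). The width of that Gaussian is not
  fixed by convention; the default is 0.3 times the per-sample standard
  deviation of observed values (`minprob_sigma_scale`), configurable.
* In the alternative `zero` mode, MNAR cells are set to 0 instead, which
  deliberately over-weights sites absent in one condition but present in
  the other.

Observed values are never altered by imputation, and all draws are governed
by a mandatory seed. Sites with at most one observed value across all
samples carry no usable quantitative information and are dropped before the
statistics.

The stage order is fixed: filter → log2 → quantile → drop under-quantified →
impute. Running the drop before imputation is the only defensible order
(imputation would otherwise invent the entire row); normalizing before
imputation keeps the MinProb quantiles on a comparable scale across samples.

## Differential testing and ranking

Each site is tested with a two-sided Welch (unequal-variance) *t*-test
between the test and reference conditions, with Welch–Satterthwaite degrees
of freedom; the log2 fold change is the difference of group means. For
multi-condition designs, `one_vs_rest()` contrasts one condition against the
others; the default pools all remaining replicates into one Welch group —
pooling preserves the within-group variance the test needs — while a
`mean_of_means` option uses per-condition means as the reference values
instead.

No significance cutoff is applied. Both direction-specific rankings contain
the full site universe, ordered by the signed score
`sign(log2fc) * (-log10 p)` — descending for the over-ranking, ascending for
the under-ranking — with ties broken by absolute fold change and then site
key, so the order is deterministic and independent of input order.

With triplicates the Welch–Satterthwaite approximation is slightly
conservative in the tails: on 10,000 simulated null sites the
Kolmogorov–Smirnov distance of the p-values from uniformity stays below
0.05 at 3v3 (but not always below 0.02) and falls below 0.02 from five
replicates per group. The
enrichment consumes ranks, not raw p-values, so this has no effect on the
kinase-level inference; it is visible only if the site-level p-values are
used directly.

## The kinase–substrate meta-database

Experimentally observed kinase–substrate associations are read from the five
public resources (PhosphoSitePlus, HPRD, RegPhos, Signor, phospho.ELM), each
through a per-source column mapping that is configuration, not code, so
snapshot drift is absorbed without edits. Human entries are kept where a
source is multi-species; in-vitro-only reactions can be excluded per source.
Kinase names are unified to HGNC symbols through a curated, user-replaceable
synonym table; (kinase, substrate) duplicates are merged with a union of
their sources; kinases left with a single entry are removed (one substrate
cannot support an enrichment). No source database content is bundled with
the package — licensing differs per resource — so tests and demos use a
synthetic database written in the same dialects.

Motif-based predictions (NetworKIN output) can be merged in, restricted to
the measured sites and to a minimum prediction score (default 2.0 — a
permissive, widely used value; results depend on it, so it is exposed
prominently). Experimental evidence takes precedence on conflicts, and the
single-entry rule is re-applied after the merge. Substrates are matched on
(gene, residue, position), ignoring multiplicity, because the databases do
not encode multiplicity.

## Enrichment: exact mHG with overlap elimination

**Primary statistic.** For a kinase whose measured substrate set has size
*K* in a ranked universe of size *N*, every prefix length *t* yields a
hypergeometric upper-tail probability of seeing at least *k_t* substrates in
the top *t*. The minimum tail over all prefixes is the
minimum-hypergeometric (mHG) statistic — a cutoff-free ranked-set test that
scans all thresholds instead of fixing one. Because the scan itself inflates
significance, the reported p-value is the *exact* null probability of the
statistic, computed by the standard dynamic program over the (prefix,
member-count) lattice — no Bonferroni-style approximation. The dynamic
program is implemented in C++ in probability space (the hypergeometric
lattice walk), so no log-space bookkeeping is needed and thousands of
evaluations per second are possible at realistic sizes. Values below roughly
1e-15 are limited by floating-point cancellation in `1 - P(avoid)`; they are
reported as ~1e-15, which is irrelevant at the 0.01 decision threshold.
Exactness is verified in the test suite against exhaustive enumeration of
all placements for N ≤ 12, K ≤ 4.

**Set-dependence graph.** Kinase sets overlap (shared substrates,
promiscuous sites), so one genuinely active kinase can drag its neighbours
into significance. All sets with primary p ≤ `set_p_cutoff` (default 0.01)
become nodes. For each overlapping pair (A, B), each set's p-value is
recomputed with the other's members removed from both the set and the
universe. An edge A → B ("A explains B") is recorded when the reduced B
loses significance while the reduced A keeps it. When *both* reductions lose
significance — mutually overlap-dependent sets, the nested decoy being the
canonical case — the set with the smaller primary p-value explains the
other (ties: smaller set, then name). This refinement is needed because a
naive "B∖A not significant ⇒ edge" rule makes nested significant sets
annihilate each other (A ⊂ B implies A∖B is empty and thus never
significant). A node is discarded only when removing the union of all its
in-neighbors' members destroys its significance; the whole procedure is
order-independent, and retained/discarded labels are verified in tests by
direct recomputation.

**Scoring and error control.** Retained nodes are scored by PageRank
(damping 0.85, power iteration to 1e-10) on the *reversed* dependence graph,
so sets that explain others accumulate score; scores sum to one. Each
kinase's p-value is Bonferroni-corrected by the number of sets tested, and a
per-kinase FDR is estimated by Monte-Carlo: the ranked list is permuted
`B_null = 100` times (seeded), every set's exact mHG p is recomputed, and
the FDR at a kinase's observed p is the mean number of null set p-values at
or below it divided by the observed count at that level, clipped to [0, 1].
A kinase is *reported* when it is retained, primary p ≤ 0.01 and
FDR ≤ 0.05. Both directions are run with the same seed, which makes the
over/under tables exactly swap when all fold changes are negated — a
property the test suite asserts literally.

The primary test is deliberately pluggable at the function level
(`primary_set_pvalue()` is a plain function over a ranked list and a member
set), so a fixed-cutoff Fisher variant can be substituted for comparison
without touching the surrounding machinery.

## What the synthetic data emulates — and what it does not

`simulate_dataset()` generates a complete MaxQuant-style dataset: log-normal
site intensities (baseline log2 intensity N(23, 2), the typical magnitude of
MaxQuant site intensities), S/T/Y residue frequencies of 80.5 / 15.8 /
3.75 % (the composition TiO2-enriched experiments typically report),
multiplicities 1/2/3 at 0.80/0.15/0.05, localization probabilities
U(0.85, 1) for genuine rows, and injected contaminant / reverse /
poorly-localized rows at 2 / 2 / 5 % that the filters must remove. Planted
kinases shift their substrates by ±`effect_size` log2 units in the test
condition. Missingness combines sporadic MAR dropout (rate 0.03 per cell)
with intensity-dependent left-censoring: the dropout probability is
logistic in the cell's log2 intensity, centred 2.5 baseline SDs below the
baseline mean with scale 0.3 — the left-censoring model that justifies
MinProb imputation. Emitted files round-trip bit-exactly through the
parsers (intensities are written as integers, localization probabilities at
full precision), so the generator doubles as the parsing oracle.

The default demo scale is 2,000 sites, 50 kinases × 15 substrates, 3 active,
3v3 replicates; the recovery benchmarks use 1,000 sites, 3 planted kinases
with 20 substrates each (+1.5 log2, noise SD 0.5) among 40 decoys. On that
scenario the full pipeline recovers essentially all planted kinases with the
correct direction and almost no decoys, and a null configuration reports on
average ≪ 1 kinase — these numbers are recomputed, not asserted, by
`scripts/acceptance.R` and the test suite.

Deliberate simplifications: substrate sets are disjoint (real kinase sets
overlap heavily — the overlap machinery is therefore exercised by dedicated
constructed fixtures rather than by the generator); noise is homoscedastic
normal on the log2 scale (no intensity-dependent variance, no batch
effects); one cell may be censored while its replicates are not, so
left-censoring occasionally *presents* as single-replicate MAR — the
count-based classifier then labels it MAR by construction, which is the
documented tolerance (≈1 % of (site, condition) pairs at default rates) in
the generator/classifier agreement check. Passing these tests therefore
demonstrates correctness of the machinery under the stated generative model,
not performance on any particular real dataset, where database coverage
(typically only ~5 % of measured sites have an experimentally known kinase,
rising to ~25 % with predictions) is the binding constraint.

## Numerical and degenerate-input choices

* Zero intensities are missing by definition; a positive-value check guards
  the log2 transform.
* A single-sample matrix cannot be quantile-normalized and is returned
  unchanged with a warning.
* A sample with fewer than two observed values has no defined 0.01-quantile;
  MinProb imputation refuses it.
* Welch tests require two usable values per group per site; other sites are
  dropped with a logged count. Identical groups yield t = 0, p = 1 (pooled
  degrees of freedom are substituted where the variance is exactly zero).
* p-values are floored at the smallest positive double before taking
  −log10.
* Empty enrichment graphs, empty waterfalls and empty prediction lists are
  legal and return empty objects rather than errors.
* FDR estimates with fewer than 10 permutations are flagged as unstable.

## Reproducibility and problem sizes

Every stochastic step — MNAR draws, FDR permutations, the generator — takes
an explicit seed, and the pipeline driver threads one seed through all of
them, making run directories bit-reproducible. The shipped validation sizes
(25-seed recovery benchmark at 1,000 sites, 20-seed null calibration,
exhaustive mHG enumeration to N = 12) were chosen so the whole suite
completes in about a minute on a laptop while keeping the Monte-Carlo
standard errors well below the margins being asserted.

## Known limitations

* Kinase activity is inferred from substrate phosphorylation only; no
  correction for protein-level abundance changes is attempted.
* Phosphatases are not modelled at all.
* The database-dependent bias is inherited: well-studied kinases have more
  annotated substrates and are easier to detect.
* The FDR is a permutation estimate, not an analytic guarantee; with the
  default 100 permutations its granularity is limited.
* The mHG p-value is exact under exchangeability of the ranked list; strong
  correlation between substrate sites of the same protein violates this
  mildly.
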