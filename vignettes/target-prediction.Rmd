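---
title: "Connectivity-based target prediction: models, parameters and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Connectivity-based target prediction: models, parameters and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(targetmap)
```

## The problem

Herbal formulas and other multi-component perturbagens act through many
protein targets at once, and most of those targets are unknown. Two
complementary kinds of evidence constrain them: the transcriptional
footprint a treatment leaves (which reflects *effect* — the targets whose
activity the treatment changes, directly or downstream), and
compound–protein *binding* (which reflects physical interaction but says
nothing about functional consequence). `targetmap` implements a workflow
that combines both: it scores a ranked differential-expression query
against a library of target-specific gene signatures to call effect
targets, trains a sequence-based classifier to call binding targets, and
intersects the two — direct targets bind *and* act; the remaining effect
targets are indirect, regulated downstream.

## Target-specific consensus signatures

Each target is represented by replicate perturbation profiles (e.g.
knock-down, over-expression or compound treatments annotated to that
target). Replicates are aggregated into one consensus profile by a
weighted average, where a replicate's weight is the sum of its pairwise
Spearman correlations with the other replicates, clipped below at 0.01
and normalized to sum to one. The clipping keeps an anticorrelated or
uncorrelated replicate from receiving a negative or zero weight; the
correlation weighting means discordant replicates are down-weighted
rather than vetoed. One consequence worth knowing: if replicates are
mutually uncorrelated, an exact duplicate pair dominates the weights
(its within-pair correlation is 1 against everyone else's clip level),
so the scheme presumes replicate-like, concordant inputs. Aggregation
uses the intersection of the replicates' gene universes; genes missing
from any replicate are dropped and counted.

From the consensus profile, the signature is the top *n* genes (`t_up`)
and bottom *n* genes (`t_down`) by value. Ties are broken by input gene
order (stable sort), so extraction is deterministic.

### Choosing the signature size

Mean |ETS| across a library shrinks as *n* grows, with diminishing
change. The decrease rate DR at size *s* is the absolute relative change
of mean |ETS| between *s* and the next size on the grid; `choose_size()`
returns the smallest size with DR at or below 0.01 (full-scale grid
100–1000 in steps of 50, where the plateau sits near *n* = 350, the
library default). We use the *absolute* relative change: the literal
difference-over-mean expression is negative for a shrinking sequence
while a "rate of decrease" is naturally reported positive. If no size
reaches the threshold, the largest evaluated size is returned with a
warning rather than an error, since a flat-enough plateau may simply lie
beyond the grid.

## The effect target score

A query is a gene list ranked in descending order of a differential
metric (signal-to-noise, log fold change). For a gene set $S$ along a
ranked list $L$ of $G$ genes with $h = |S \cap L|$ hits, the enrichment
score $ES(L, S)$ is the signed extremum of the running sum that rises by
$1/h$ at each hit and falls by $1/(G-h)$ at each miss — a
Kolmogorov–Smirnov-style maximum deviation. The effect target score for
signature $(t_{up}, t_{down})$ is

$$ ETS_L^t = \frac{ES_L^{up} - ES_L^{down}}{2}, $$

set to 0 when $ES_L^{up}$ and $ES_L^{down}$ share a strict sign: if both
halves of a signature drift the same way the score carries no
directional evidence. $ETS = +1$ means `t_up` occupies the very top of
the query and `t_down` the very bottom (the query activates the target's
program); $-1$ the mirror image (the query reverses it).

Numerical choices:

* The running sum is unweighted by default (rank-only), matching the
  connectivity-mapping convention; a metric-weighted variant (weight
  exponent 1) is available via `weighted = TRUE`.
* The extremum is the prefix value of largest absolute value, signed.
  When the maximum and the minimum tie in magnitude the earlier prefix
  wins, which is what a literal top-to-bottom scan yields. Internally
  the sum is evaluated in exact integer units of $1/(h(G-h))$, so these
  ties are decided exactly, never by floating-point accidents.
* Signature genes absent from the query are dropped per side; a side
  matching fewer than half its genes flags the result as low-coverage,
  and a side with no overlap contributes 0.

## Permutation calibration: p, NETS, FDR

Significance comes from permuting the query's gene labels (equivalently,
placing the matched signature genes at uniformly random ranks — overlap
counts are preserved, which is why the permutation can be sampled
directly and cheaply). Per target, 1000 permutations by default. The
nominal p compares the actual ETS with the same-sign portion of its
null: for a nonnegative score, the fraction of nonnegative null values
at or above it. A zero numerator is floored at one over the same-sign
count, so finite permutation never reports p = 0.

The normalized score $NETS = ETS / |\mathrm{mean}(\text{same-sign
null})|$ makes scores comparable across signatures of different sizes
and across queries; we divide by the *absolute* mean so that the sign of
NETS always equals the sign of ETS (dividing a negative score by a
negative mean would silently flip it).

The FDR at a given NETS is the ratio $A/B$ of two same-sign tail
fractions, $A$ in the null NETS pooled across **all** targets and all
permutations, $B$ among the actual NETS of all targets, clipped at 1.
Pooling across targets follows from treating the normalized scores as
exchangeable across signatures — that is what the normalization is for.
A NETS of exactly 0 carries no direction and is assigned FDR 1. The raw
$A/B$ ratio is reported as defined, without a monotone envelope: it can
occasionally step upward as |NETS| grows, because the denominator drops
in steps of one actual observation. Consumers who need a monotone
quantity can apply a running minimum per sign.

### Known behaviour of the nominal p under a global null

Because the zero rule censors roughly half of all scores under a
pure-noise query (the two one-sided scores share a sign about half the
time), those targets receive p = 1 exactly. The p distribution across
targets is therefore *conservative*, not uniform: its small-p tail is
calibrated (about 5% of targets at p ≤ 0.05, which the acceptance suite
checks at 500 targets × 1000 permutations), but there is a large atom at
p = 1. Any test that expects the full p distribution to be uniform will
reject; this is a structural property of the censored score, not a
calibration defect.

## The binding classifier

The binding module predicts whether a compound (canonical SMILES) binds
a protein (amino-acid sequence). Each pair is encoded by character
n-gram counts (k = 1–3) of its two sequences — the natural linear-algebra
form of local-motif detectors over character strings — with the n-gram
vocabulary learned from the training split (grams occurring in at least
two sequences, capped at 2000 per branch), log-scaled and standardized.
A small feed-forward network (hidden layers 64/32, sigmoid output) is
trained by mini-batch Adam under binary cross-entropy; learning rate
8e-4 and batch size 256 by default, 30 epochs at desk scale (the
full-scale recipe uses 100). Training reports per-epoch loss; an 80/10/10
train/validation/test split by pair (seeded) yields held-out AUROC and
AUPR. Everything is deterministic given the seed.

Interaction catalogs list only positives, so negatives are sampled
uniformly from unobserved compound–protein combinations at 1:1
(`sample_negative_pairs()`), a choice documented here as this package's
own. Binding targets are called at score ≥ 0.90, the high-confidence
operating point for herb-level calling, where an herb's binding set is
the union over its component compounds.

## Target algebra and networks

* **Effect targets**: FDR ≤ 0.05 (inclusive) in the connectivity results.
* **Reversal (therapeutic) targets**: significant in *both* the drug and
  the disease queries with strictly opposite NETS signs. A NETS of 0 on
  either side excludes the target — zero carries no direction. Requiring
  two-sided significance (rather than one side plus an opposite sign) is
  the stricter reading and the one implemented.
* **Direct / indirect**: direct = effect ∩ binding; indirect = effect
  \ binding. The two always partition the effect set.
* **Component–target network**: bipartite compound→direct-target edges
  from the binding calls; compounds rank by degree, ties broken
  lexicographically for reproducibility. High-impact targets are those
  with |NETS| ≥ 4.
* Query similarity is the Pearson correlation of NETS vectors over
  shared targets, optionally restricted (e.g. to the reversal set).

## Over-representation analysis

Pathway mapping is a hypergeometric upper-tail test per gene set with
Benjamini–Hochberg correction across the tested sets. The universe is
the collection's declared universe (by default the union of set
members, intersected with any user-supplied universe): ORA is only valid
when the universe is the space the query was drawn from, which for this
workflow is the scored target space, not the whole genome. Query genes
outside the universe are dropped (and counted) before the query size is
fixed; sets smaller than 5 or larger than 2000 members are skipped by
default, standard ORA practice. Enriched pathways are annotated with
their direct and indirect member targets, which changes no statistic.

## The synthetic-data generator

`simulation_config()` fixes the study conditions used throughout the
test suite: 2000 genes, 50 targets, 5 replicates per target, planted
up/down blocks of 20 genes, effect size 3 in noise-SD units, unit
Gaussian noise, 1000 permutations. These are desk-scale stand-ins for a
full signature library (thousands of targets over a ~10,000-gene space)
chosen so that planted signal is strong but not trivial: a 3-SD shift
averaged over 5 replicates separates block genes from background with
high probability while single-replicate recovery stays imperfect.
Queries activate or reverse chosen targets; the drug-as-negation
construction mirrors a treatment that reverses a disease signature. The
binding generator plants a two-motif AND rule (a SMILES fragment motif
and a protein sequence motif, carrier rates set so positives are
balanced) with 1% label noise; gene sets overlap planted blocks at a
configurable fraction. All randomness flows from one master seed through
named substreams, so each piece can be regenerated independently.

What the generator does **not** emulate: the landmark/inferred gene
structure of real expression platforms, correlated backgrounds between
targets, chemically valid SMILES beyond tokenizer compatibility, or
homology structure among proteins. Passing recovery tests therefore
demonstrates the statistical machinery — signal propagation from
replicates through consensus, scoring, calibration and classification —
not performance on real data.

## Validation scale

The heavier checks run at fixed sizes chosen as this package's own
validation conditions: null calibration at 500 targets over a
20,000-gene universe with 1000 permutations; recovery at the default
50-target configuration with 5 active targets; a 10,000-pair randomized
stress suite for the |ETS| ≤ 1 bound; exhaustive enumeration of every
running-sum case with universes up to 12 genes and sets up to 4; the
binding learnability run at 2000 pairs. `scripts/acceptance.R`
recomputes the headline quantities from scratch at these sizes.

## Known limitations

* The nominal p is conservative under the global null (atom at 1; see
  above), and the raw pooled FDR is not guaranteed monotone in |NETS|.
* Whether over-expression perturbations should be sign-flipped before
  averaging into a consensus is biologically ambiguous; profiles are
  aggregated as given, with a per-type sign option
  (`build_signature_library(type_signs = c(OE = -1))`) for callers who
  want the flip.
* The binding classifier is a desk-scale model: n-gram detectors capture
  local sequence motifs well, but nothing here claims parity with
  large-scale interaction models trained on full interaction databases.
* Gene identifiers are opaque strings; no cross-vocabulary mapping is
  attempted anywhere.
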