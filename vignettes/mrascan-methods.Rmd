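---
title: "Methods: network inference, master regulator analysis and promoter scanning in mrascan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: network inference, master regulator analysis and promoter scanning in mrascan}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mrascan)
```

# The problem

Rare, transient cell states — the motivating example is the
Zscan4-positive, 2-cell-embryo-like metastate of mouse embryonic stem
cells and its induction by retinoic acid — are driven by transcription
factors (TFs) that are hard to find by differential expression alone,
because the factors themselves need not change strongly while their
target programs do. `mrascan` implements the standard in-silico strategy
for this situation:

1. infer a genome-wide TF–gene network from an expression compendium
   (mutual information, indirect-edge pruning, permutation FDR);
2. ask which TF's inferred regulon is enriched in a ranked
   differential-expression signature of the state of interest (master
   regulator analysis, MRA);
3. keep only master regulators whose binding motif actually occurs in
   the target gene's promoter (PWM scanning with normalized scores and
   exact p-values).

The intersection of (2) and (3) is the direct-regulator shortlist. Every
stage is exercised end to end on synthetic data with planted ground
truth, so the statistical behaviour of the whole chain is testable
without any external download.

# Expression preprocessing

Compendia are quantile-normalized (every condition is forced onto the
mean of the sorted columns; ties receive the mean of the normalized
values at their tied ranks, via `limma::normalizeQuantiles`). Probe-level
matrices are collapsed to genes by the arithmetic mean of all retained
probes; control probes and probes without a gene symbol are dropped. No
probe-level significance filter is applied — "redundant probes" is read
as "all retained annotated probes of the gene"; a stricter notion can be
emulated by pre-filtering the annotation table. Missing values are
rejected at load time rather than imputed: the mutual-information
estimator below assumes complete paired observations. Normalization is
applied at whatever level the matrix is loaded; when both steps are
needed, normalize first and collapse second (the listed order of the
procedure).

# Network inference

## The mutual-information estimator

With `n` conditions, both profiles are rank-transformed (ties broken by
observation order, so the estimate is deterministic and invariant under
strictly monotone transforms of either input) and discretized into
`B = floor(n^(1/3))` equal-frequency bins (minimum 2). The plug-in
mutual information of the `B × B` contingency table is computed in nats
and corrected for discretization bias with the Miller–Madow term
`(m_xy − m_x − m_y + 1) / (2n)` (occupied-cell counts), then clamped at
zero.

The bin count deserves a note. A popular rule of thumb, `B = sqrt(n)`,
makes the first-order plug-in bias `(B − 1)^2 / (2n)` approximately
`1/2` nat *independently of n* — at `n = 50{,}000` that is a bias an
order of magnitude larger than the quantities being estimated. The
cube-root rule keeps the bias term `O(n^{-1/3})` while the
equal-frequency quantization error also vanishes with `B`; combined
with the Miller–Madow correction, the estimator matches the
bivariate-Gaussian closed form `−½·ln(1 − ρ²)` to within a few
hundredths of a nat across ρ from 0 to 0.9 at large n (this is asserted
by the test suite at n = 50,000, tolerance 0.05 nats). At the small
`n = 100`–`120` used in the synthetic compendia, `B = 4`–`5`; absolute
accuracy is poor there, but the permutation test below compares each
observed value against its own permutation null, so only ranking
behaviour matters.

Constant profiles return MI = 0 with a warning. The estimator is
symmetric and nonnegative by construction.

## Candidate edges

One edge per (TF, gene) pair with `tf ≠ target`; TF–TF pairs enter once
as unordered pairs. For `t` TFs among `g` matrix rows this gives
`t·(g − t) + t·(t − 1)/2` candidate links, in deterministic
(tf, target) order.

## Data processing inequality (DPI)

For a Markov chain X → Y → Z, `MI(X,Z) ≤ min(MI(X,Y), MI(Y,Z))`, so in
a fully connected triplet the weakest edge is the prime suspect for
being indirect. `apply_dpi()` examines every triplet whose three
pairwise edges are all present and removes the edge with the *strictly*
smallest MI when it falls below `min(other two) × (1 − tolerance)`.
Three decisions matter:

* **tolerance defaults to 0** (strict): the conservative reading when no
  tolerance is prescribed; it removes exactly the strict minimum of each
  triangle.
* **ties remove nothing**: with no strict minimum there is no principled
  victim.
* **one pass against the original weights**: all removal decisions are
  evaluated on the input edge set, not incrementally, so the result is
  independent of triangle enumeration order.

Edges outside any complete triangle are never touched. Note that a
chain shortcut can only be pruned if the intermediate is itself in the
TF list — otherwise the intermediate–target pair is never scored and no
triangle exists. This mirrors the behaviour of compendium-scale
MI-network methods.

## Permutation FDR

After DPI (the literal step order of the three-stage procedure), each
surviving link gets its own null distribution: the target profile is
randomly permuted `n_permutations` times (default 1,000) and the MI
recomputed. The p-value uses the add-one estimator
`p = (1 + #{null ≥ observed}) / (n_permutations + 1)`, which is never
exactly zero and hence valid for Benjamini–Hochberg adjustment across
all tested links; links with `q ≤ 0.01` are retained. The permutation
loop is compiled (Rcpp) and driven by R's seeded RNG, so identical
seeds give identical p-values. A pooled-null mode (null MIs shared
across links) is available as a documented approximation for very large
edge sets; the per-link mode is the default and the literal reading of
the procedure.

A structural consequence worth knowing: with 1,000 permutations the
smallest attainable p-value is `1/1001`, so on a *fully null* matrix
with thousands of candidate links the BH rank-1 cutoff (`0.01/m`) is
unreachable and the retained fraction is essentially zero — FDR control
on null data holds by construction, which the acceptance suite verifies
empirically (20 TFs × 200 genes, 100 conditions, 20 seeds).

# Master regulator analysis

## Regulons

A TF's regulon is every gene connected to it in the final network;
TF–TF edges contribute each factor to the other's regulon. Regulons
smaller than `min_regulon_size` (default 10) are not tested: the
enrichment statistic degenerates for tiny sets, and no principled
minimum is prescribed, so the threshold is exposed.

## Enrichment score

The classic weighted Kolmogorov–Smirnov running sum: walking down the
signature (sorted descending, ties broken by gene id), regulon members
increment by `|s|^α / Σ_hits |s|^α` and non-members decrement by
`1/(N − N_hits)`; the enrichment score (ES) is the running-sum value of
maximal absolute deviation, first such position on ties, so
`ES ∈ [−1, 1]`. The weight exponent α defaults to 1 (classic weighted
GSEA) and is configurable. The implementation is checked in the test
suite against an independent brute-force loop (200 random instances, at
floating-point accumulation accuracy) and against `fgsea::calcGseaStat`.

## Null model, p-values and NES

The pipeline receives a *precomputed ranked signature*, not
sample-level data, so the only implementable null is gene-label
permutation: regulon membership is reassigned to random gene sets of
equal size (10,000 permutations by default). Positive and negative
sides are treated separately, compatible with signed regulation:

* `p = (1 + #{same-sign null with |ES_null| ≥ |ES|}) / (n_same_sign + 1)`
* `NES = ES / mean(|ES_null| of the same sign)`

so `sign(NES) = sign(ES)`. Fewer than 10 same-sign null scores triggers
a degeneracy warning. BH adjustment runs over all tested TFs;
`q ≤ 0.01` defines the *candidate* set.

## The master-regulator filter

A master regulator is a candidate with `p ≤ 0.001` and `|NES|`
*strictly greater* than the 70th percentile (nearest-rank) of `|NES|`.
The population over which that percentile is taken is genuinely
ambiguous in the procedure this package follows; `mrascan` computes it
over **all tested TFs** by default, with `"candidates"` exposed as an
option. The deciding argument is degeneracy: over candidates, a run in
which the true regulator is the *only* candidate (exactly the situation
a strong, specific signature produces) can never flag anything, because
the sole |NES| cannot strictly exceed its own 70th percentile — the
filter would be unsatisfiable precisely when the signal is cleanest.
Over tested TFs the filter behaves monotonely in signal strength, and
the single-tested-TF edge case still (correctly) flags nothing.

# Promoter motif scanning

## Motif models

A motif is a 4 × L base-frequency matrix with a flat per-cell
pseudocount: probabilities are `(count + pc) / (column total + 4·pc)`.
IUPAC consensus strings convert symbol-wise to uniform distributions
over each symbol's base set (R → A/G at ½ each) before the pseudocount.
Log-odds are `ln(prob / background)`; the background defaults to
uniform (0.25 each), matching the simplest scanning null and the
brute-force enumeration oracle used in tests, and can be overridden
(e.g. with the scanned sequence's composition).

## Normalized binding score

`(raw − min attainable) / (max attainable − min attainable)`: the only
bounded [0, 1] convention, attaining exactly 1 on the column-wise
argmax word and 0 on the argmin word. The binding threshold 0.7 and the
match p-value threshold `1e−4` are the method's standard operating
point and are exposed as parameters.

## Exact p-values by dynamic programming

`P(random background word scores ≥ t)` is computed on an integer
lattice: each log-odds entry is floored to a multiple of the
granularity g (default `1e−3`), and the exact distribution of the
lattice score is built by column-wise convolution. Flooring makes the
returned tail a *guaranteed upper bound* on the infinite-precision
p-value; the same distribution read at `ceiling(t/g)` gives the
matching lower bound, so the truth is bracketed within
`(L + 1)·g` on the score axis. When a decision threshold is supplied
and the bracket straddles it, the granularity is refined 4-fold (up to
3 times) until the decision is unambiguous. The test suite checks the
bracket against exhaustive enumeration of all `4^L` words for motifs up
to L = 8.

## Scanning conventions

All coordinates are 0-based, half-open, reported on the forward strand;
a minus-strand hit means the reverse complement of the interval matches
the motif. Windows containing ambiguous bases (N) are skipped with a
message rather than scored arbitrarily. `fimo_scan()` scores every
window on both strands, converts scores to lattice p-values with a
single dynamic program per call, and applies BH over all positions
scanned in that call (a deliberate, documented simplification relative
to the cited tool family's internal q-value machinery — one multiple
testing method is used across the whole package), returning hits with
`q` strictly below the threshold (default 0.1).

## Promoters and the RA-responsive window

Promoter regions are fixed-length windows upstream of the TSS
(conventional lengths 2,400, 480 and 288 bp), reverse-complemented for
minus-strand genes so the returned sequence always ends adjacent to the
TSS. The retinoic-acid-responsive region is the TSS-relative window
`[−480, −288)` — inclusive at the upstream bound, exclusive at the
downstream bound, a convention this package fixes because only the
bp figures themselves are prescribed; a hit is "in" the window if it
overlaps it by at least one base. The default RARE motif set is the
direct repeats DR1/DR2/DR5 of the RGKTCA half-site with spacers of 1, 2
and 5 bp, supplied as editable IUPAC strings (the canonical consensus
family; any motif collection can be substituted).

# The pipeline and the direct-regulator intersection

`run_pipeline()` chains normalize → infer → MRA → scan. A TF is a
promoter *binder* if it has at least one hit with normalized score
≥ 0.7 and p ≤ 1e−4 in the configured window; the direct-regulator
shortlist is the intersection of flagged master regulators and binders.
TF-to-motif mapping is an explicit input table — no name-matching
heuristics — and master regulators without a mapped motif are reported
"unscannable", never silently dropped. Whether binding is judged on the
full 2,400 bp promoter or restricted to the RA-responsive window is
exposed as a switch (`restrict_to_rar_window`), since both readings of
the procedure are defensible. Every stage writes its artifact
(normalized matrix, network TSV, MRA table, hit BEDs, JSON report), the
report contains the config snapshot and seed, and identical config +
seed reproduce the report byte for byte.

# The synthetic-data generator

The generator emulates the *structure* the inference assumes, not any
particular microarray experiment:

* **Network**: each of `n_tf` TFs gets a regulon of 12–18 non-TF genes
  (sizes uniform in the configured range) with activating weights
  uniform in 0.6–1.0; a configurable fraction of targets (default 20%
  in the shipped fixture) are second-order chains TF → intermediate →
  target with no direct edge — the structure DPI is meant to prune.
* **Compendium**: TFs are independent standard normals per condition,
  shifted by ±3 in 2 dedicated over-expression and 2 knock-down
  conditions each (mirroring an over/under-expression perturbation
  compendium without modelling specific experiments); regulated genes
  are weighted sums of their parents plus Gaussian noise (sd 0.5), so
  zero noise yields exact linear relations and the TF–target
  correlation has the closed form `w/sqrt(w² + σ²)`.
* **Signature**: members of the planted master regulator's regulon draw
  ranking scores `N(effect, 1)` (effect 10 in the fixture — a
  cleanly separated signature), everyone else `N(0, 1)`.
* **Promoters**: i.i.d. background sequence with motif *consensus*
  words written at recorded non-overlapping positions and uniformly
  chosen strands (reverse complement on the minus strand). Writing the
  consensus rather than sampling from the PWM makes
  normalized-score-equals-1 recovery exact; sampling is available as an
  option.

Everything is a pure function of (parameters, seed). What the generator
deliberately does **not** model: probe-level artifacts, batch effects,
chip layouts, heteroscedastic or non-Gaussian noise, repressive
(negative-weight) regulation, cooperative or overlapping binding sites,
and realistic promoter base composition. Passing tests therefore
demonstrate the statistical machinery is correct and calibrated under
the linear-Gaussian planted model — not that any particular biological
compendium will yield a particular network.

# Problem sizes used by the tests

The shipped fixture and test suite run at desk scale, chosen so the
full suite and the acceptance script each complete comfortably on a
single CPU: 20 TFs × 200 genes × 120 conditions with 1,000 network
permutations and 10,000 MRA permutations for the end-to-end fixture;
20 replicate 220 × 100 null matrices for FDR control; n = 50,000 for
the Gaussian MI check; 100 seeded replicates for the DPI-chain and
background-RARE Monte Carlos; motifs up to L = 8 for exhaustive
p-value enumeration. The compendium-scale run (thousands of TFs, tens
of thousands of genes) is out of scope; the per-link permutation core
is compiled, and the pooled-null mode exists precisely to make larger
instances tractable.

# Known limitations

* MI is unsigned; activation cannot be distinguished from repression,
  so regulon "direction" is not used in any filter (the correlation
  sign can be attached as edge metadata by the user).
* The binned estimator's absolute accuracy at n ≲ 100 conditions is
  coarse; inference there rests on the permutation null, not on the MI
  values themselves.
* Gene-label permutation is a weaker null than phenotype permutation;
  with strongly correlated regulon members it can be anti-conservative.
  It is the only null available to a pipeline whose input is a ranked
  list.
* BH is used for the scanning q-values where the cited tool family uses
  a different estimator; q-values here are conservative relative to
  Storey-type estimates.
* The DP p-value is an upper bound within its bracket; at the default
  granularity the bracket is far narrower than any decision threshold
  used by the pipeline.
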