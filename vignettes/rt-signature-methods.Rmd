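---
title: "RT-signature methods: model, parameters and design choices"
author: "rtsig"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{RT-signature methods: model, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

# The signature model

m¹A methylates the Watson–Crick face of adenine, so a reverse transcriptase
that reaches it on the template either stalls or misreads. In aligned,
template-sense RNA-Seq data, the two outcomes appear as:

* an excess of reads whose leftmost reference position is `p + 1` — the cDNA
  was synthesized from the fragment's 3′ end down to `p + 1` and aborted
  before copying `p`;
* non-reference base calls at `p` in reads that bypassed the site.

All statistics in this package are defined over these observables.

**Arrest rate.** `a(p) = e(p+1) / c(p+1)`, where `e(p+1)` counts reads whose
leftmost position is `p+1` and `c(p+1)` is coverage at `p+1`. The denominator
deliberately uses `p+1`, not `p`: arrested and read-through molecules both
cover `p+1`, so the ratio is the conditional probability that a molecule
which reached the site failed to cross it. Under the generative model with
occupancy `f` (fraction of molecules modified) and arrest probability
`p_arr`, `E[a(p)] = f · p_arr` wherever no fragment starts naturally at
`p+1` (see *Simulator geometry* below).

**Mismatch rate and composition.** `m(p)` is the share of non-reference
A/C/G/T calls among all A/C/G/T calls at `p`. `N` calls and deletions are
excluded from numerator and denominator: they carry no substitution
information. The composition splits the mismatched calls over the three
non-reference bases (reported as G/T/C for a reference adenosine,
template-sense). Its expectation among reads covering `p` is
`f(1−p_arr)·q / (1−f·p_arr)`, with `q` the off-reference mass of the
read-through emission distribution.

**CSA.** The context-sensitive arrest rate is the fold change of `a(p)`
against the mean arrest rate over positions `p−5 … p+5`, excluding `p`
itself and truncating at reference boundaries. Excluding the center keeps a
strong site from damping its own fold change; the choice is exposed via the
`window` argument. Neighbors with undefined arrest rates are ignored; a zero
neighborhood mean is guarded with ε = 10⁻³ and flagged.

**Undefined ratios.** Zero denominators (no coverage at `p+1`, no A/C/G/T
calls at `p`, empty CSA neighborhood) never propagate NaN. The value is
reported as 0 together with an explicit flag
(`arrest_undefined`, `mismatch_undefined`, `csa_*`), so downstream filters
can exclude such positions deterministically.

# Feature set and classifier

Each adenosine passing the coverage filters — site coverage ≥ 10 and
3′-adjacent coverage ≥ 15, the position where arrest manifests — yields the
seven features `a`, `m`, `m/a`, `comp_G`, `comp_T`, `comp_C`, `CSA`. The +1
base identity is deliberately *not* a feature, to avoid training the
classifier on sequence context rather than signature shape. `m/a` with
`a = 0` is guarded as `m/ε`, ε = 10⁻³, keeping the feature finite.

The classifier is a 500-tree random forest; all other hyperparameters follow
the implementation defaults and are echoed into every report. Class votes
are converted to labels by majority, with exact ties resolved to non-m¹A —
a conservative calling convention, since a false modification call is
usually costlier than a miss. Evaluation harnesses:

* **10 × 5-fold stratified CV** — folds preserve the class ratio within one
  instance; sensitivity/specificity are averaged over all repetition × fold
  cells with their SD.
* **Leave-one-out** over balanced pairs (one positive + one negative per
  round; `min(n_pos, n_neg)` rounds).
* **Leave-feature-out** — mode `single` drops one feature at a time; mode
  `subsets` compares the full set against arrest-only (`a`, `CSA`) and
  mismatch-only (`m`, `comp_G/T/C`) groupings. `m/a` mixes both components
  and belongs to neither single-family set.
* **kNN baseline** under the identical CV harness (features z-scaled on the
  training fold, so the euclidean metric is not dominated by the wide-range
  ratio features); k ∈ {1, 3, 5} are evaluated separately.
* **ROC** — thresholds sweep the out-of-fold positive vote fractions; the
  AUC is the trapezoid integral.

Three dataset settings mirror increasingly stringent validation: (i)
positives vs. uniformly random unmodified adenosines; (ii) positives vs.
*confusable* negatives only — records with `a ≥ 0.2`, or `m ≥ 0.2`, or
`m ≥ 0.1` with at least two mismatch types holding ≥ 0.1 share (the
three-clause rule is implemented with OR semantics, the two-type condition
tied to the `m ≥ 0.1` clause; all four thresholds are configurable); (iii)
train on tRNA-class instances, test on rRNA-class instances exclusively.
For (iii) the negative class of the test set is not prescribed anywhere; we
draw test negatives from rRNA-class adenosines so that train and test remain
reference-disjoint.

# The read simulator

The simulator is the test bed for every other module: it emits forward
strand end-to-end alignments directly (no mapper), so the ground truth is
exact.

Per molecule: a fragment 3′ end is drawn uniformly over the reference, its
length uniformly over the size-selection window (default 50–150 nt,
matching a typical excised gel band), clipped at the 5′ boundary; fragments
shorter than the window minimum are discarded, mirroring size selection.
The molecule is modified at each covered site independently with probability
`occupancy`. cDNA synthesis walks from the 3′ end toward 5′; at a modified
site the RT arrests with probability `p_arrest` (read leftmost position
becomes site + 1) or reads through, emitting a base from the site's
misincorporation distribution. All other bases suffer background
substitution at `error_rate` (default 0.001, uniform over alternatives) —
a plausible combined RT + sequencing error floor; no published value exists
for read-through error at unmodified adenosines, so this is a free
parameter.

**Simulator geometry.** The default study design uses 76-nt references with
the site at position 58 — the canonical tRNA m¹A58 location. Because the
site then lies within one minimum fragment length of the 3′ end, no
size-selected fragment can *naturally* start at position 59, and `a(58)`
estimates `f · p_arr` without background bias. This mirrors real tRNA
geometry rather than being a numerical convenience.

**Misincorporation presets.** The +1-keyed presets encode the qualitative
structure of natural m¹A sites: +1 = U (T in mapping space) drives a
T-dominated template-sense signal; +1 = G and +1 = A give mixed G/T signals
with low C share; +1 = C gives a high C share and low T. A non-zero A
component is kept throughout because the RT occasionally incorporates the
correct dTTP even opposite m¹A. No numeric composition table has been
published, so the exact values are package defaults, configurable per site.

**What the simulator does not emulate:** ligation biases, PCR duplicates,
unique molecular indices, RNA structure effects on arrest (the model's
`p_arrest` is a per-site constant, whereas in real data equally modified
sites can differ widely in arrest strength), mapper artefacts and
mismapping, and interactions between multiple modifications on one molecule
beyond independent sites. Passing tests therefore demonstrate correctness
of the statistical machinery under the stated generative model, not
robustness to every artefact of real libraries.

# Occupancy titration

Arrest depletes read-through coverage: with the per-call mismatch rate
`m = f(1−p_arr)/(1−f·p_arr)`, `m` is *not* affine in `f` when `p_arr` is
large. What is exactly affine is the **per-molecule misincorporation rate** —
mismatched calls at `p` divided by coverage at `p+1`, i.e. normalized to
molecules that reached the site — with slope `(1−p_arr)·q`. This shared
denominator is also what makes "arrest + misincorporation" a meaningful
lower bound on occupancy: both terms are then probabilities of disjoint
events on the same set of molecules. `titration_summary()` therefore
reports both quantities, and the linearity checks in the test suite are run
on the arrest rate and the per-molecule misincorporation rate; the per-call
`m(p)` is checked for monotonicity only.

# Context analysis

Redundant sites are collapsed in three steps before composition analysis:
replicate averaging per site; merging of records from references with > 95%
global-alignment identity (single-linkage components; identity = matching
columns / alignment length, end gaps penalized — the identity measure had
to be fixed here, as no standard definition is universal); and averaging of
identical (−1, +1, +2) context triples. The reduction is idempotent, and
merged provenance is retained.

Compositions are mapped to ternary coordinates with corners G = (0, 0),
T = (1, 0), C = (0.5, √3/2) — a plotting convention recorded in the output
attributes; the mapping is affine and invertible on the simplex.
Hierarchical clustering uses average linkage on euclidean distances between
composition vectors.

The separation test is an in-house permutation test (the originally
published verification procedure for this kind of clustering is not public,
and reports label the statistic accordingly): S = mean between-group
distance − mean within-group distance over +1 groups, with the add-one
smoothed p-value over label permutations. Groups with fewer than two
members contribute no within-group pairs and are noted. The test suite
calibrates its type-I error on unstructured compositions at α = 0.05.

Mismapping risk between near-identical references (tRNA isoacceptors above
all) is summarized by a unit-cost Levenshtein distance matrix; the
implementation is base R's dynamic-programming edit distance, checked in
the tests against an exponential recursive oracle.

# Numerical and I/O choices

* 1-based, closed coordinates throughout, labeled on the full reference
  length.
* Reverse-strand alignments are excluded (counted and warned): the library
  protocol is strand-preserving and a reverse alignment indicates a
  processing problem, not biology. Soft/hard-clipped alignments are
  rejected outright — mapping is expected end-to-end, and clips would
  corrupt read-start counts.
* Deletions are counted in coverage under `DEL` but excluded from mismatch
  statistics; insertions consume query only and are ignored (no reference
  coordinate).
* Profile and signature TSVs serialize fractions with 17 significant
  digits, so write → read → write is byte-identical and round trips are
  lossless; flags are comma-separated tokens, never '.'.
* Every stochastic routine takes an explicit seed; the CLI derives
  per-stage seeds from one master seed by fixed offsets so stages can be
  rerun independently and reproduce byte-identically.

# Validation design and problem sizes

The test battery simulates its own data at sizes chosen to keep binomial
noise well below the assertion margins while remaining quick to run:

* headline classifier check: 48 fully occupied sites, `p_arrest` drawn from
  0.7–0.9, depth 5000 reads per reference, balanced against random
  unmodified adenosines, 10 × 5-fold CV with 500 trees;
* closed-form parameter recovery: a 4 × 4 grid of
  (f, p_arrest) ∈ {0.25, 0.5, 0.75, 1}² at depth 10 000, requiring
  agreement within 3 binomial standard errors;
* titration: occupancies {0, 0.25, 0.5, 0.75, 1} at depth 10 000,
  requiring R² > 0.99 for the affine quantities;
* oracle equivalence: 100 randomized small alignment instances (≤ 50
  reads, ≤ 100 nt) against a brute-force per-read counter, and all pairs of
  random sequences ≤ 8 nt against the recursive edit-distance oracle;
* null calibration: label-shuffle Monte Carlo of the CV harness (10
  shuffles) and 200 null repeats of the separation test;
* feature-family ordering: a deliberately weak-signal, heterogeneous-arrest
  regime (occupancy 0.08–0.25, per-site `p_arrest` 0.02–0.98, depth 250,
  error 0.005), averaged over three independent datasets — at the headline
  conditions every family saturates and the comparison would be vacuous.

# Known limitations

* The feature definitions presume single-fragment, template-sense
  libraries; paired-end logic and mapping-quality filtering are out of
  scope, as is transcriptome-wide scanning with multiple-testing control.
* Occupancy estimation from signatures alone is semi-quantitative: the RT
  sometimes incorporates the correct base at a modified site, so
  arrest + misincorporation only bounds occupancy from below.
* Other Watson–Crick-face modifications (e.g. m⁶,⁶A) can produce signatures
  the classifier cannot distinguish from m¹A; a candidate call warrants
  orthogonal confirmation.
* The classifier generalizes only as far as its training contexts; sites in
  radically different sequence or modification contexts may be missed.
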