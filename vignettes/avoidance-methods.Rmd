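---
title: "Quantifying mRNA:ncRNA avoidance: models, nulls and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying mRNA:ncRNA avoidance: models, nulls and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rnavoid)
```

## The phenomenon and the model

Abundant non-coding RNAs (tRNA, rRNA, RNase P, SRP, tmRNA, 6S) saturate the
cytoplasm. Any mRNA whose 5' end happens to base-pair well with them pays a
translation-initiation penalty, so selection should deplete such chance
complementarity. `rnavoid` calls this depletion *avoidance* and measures it
two ways:

* **extrinsic avoidance** — the binding minimum free energies (MFE) between a
  genome's mRNA 5' regions (the first 21 nt of each CDS, where initiation is
  decided) and its core ncRNAs sit *higher* (less stable) than those of
  dinucleotide-preserving shuffles of the same mRNA regions;
* **intrinsic avoidance** — mRNA and ncRNA populations segregate in G+C
  content, which suppresses interaction capacity before sequence order even
  matters.

A genome is classified an avoider when either test is significant at
`alpha = 0.05` (strict `<`, no multiple-testing correction across genomes:
each genome is its own experiment and the claim is about the fraction of
genomes, not about any single one).

Because ncRNAs are assumed to be in large molar excess over any particular
mRNA, interaction sites are treated as saturated and interaction energies
*sum* — this is why the designer's avoidance score for a candidate mRNA is
the plain sum of its per-ncRNA binding MFEs.

## The energy engine

The engine is an intentionally simplified nearest-neighbour model, written
for this package (dynamic programming in C++), not a re-implementation of
any published folding suite. At 37 °C, in kcal/mol:

* Watson-Crick and GU pairs; helix stacking energies from a Turner-like
  rounded table (`inst/extdata/energy_params_default.tsv`);
* hairpin (minimum loop 3), bulge and interior loops penalised by total
  unpaired length, log-extrapolated beyond 30 (Jacobson–Stockmayer,
  `1.75·RT·log`);
* multibranch loops with a linear penalty `a + b·branches + c·unpaired`;
* duplexes pay an initiation cost (+4.1) and an AU/GU end penalty (0.5 per
  end); the fold model applies no helix-end penalty;
* no dangling ends, no coaxial stacking, no special hairpins, no
  loop-asymmetry term, no temperature scaling.

Interior loops are capped at 30 unpaired nucleotides in folds and 6 in
duplexes; local intermolecular duplexes with larger loops are better
described as two separate interactions, and the tight cap keeps genome-scale
scans fast. Both caps are parameters shipped in the TSV and honoured by the
brute-force oracles, so the dynamic programs are verified against exhaustive
enumeration *of the same model* (`tests/testthat/helper-oracles.R`): every
structure of short random sequences is enumerated, scored by explicit loop
decomposition, and compared with the DP optimum — exactly, on hundreds of
instances per run.

Three energies are exposed:

* `fold_mfe()` — intramolecular MFE (used on the first 37 nt for the 5'
  structure metric, the window where structure measurably affects
  expression);
* `duplex_mfe()` — intermolecular-only hybridisation (`mode = "hybrid"`);
* `interaction_energy(mode = "access")` — the pipeline default: the joint
  minimum of duplex energy plus the cost of opening the binding site inside
  each molecule's own structure. Because opening a larger site never costs
  less, the optimal site equals the duplex span, so the search enumerates
  anchored duplexes (bounded by `max_site = 25` per molecule — the site cap
  is our choice; published accessibility methods do not fix one) instead of
  all interval pairs.

Positive optima are reported as 0 ("no favourable interaction") with empty
sites. Raw interaction tools report positive optima as-is; truncation at 0
avoids sign-flip artifacts in rank tests where a *less negative* energy must
always rank as *weaker binding*. Energy ties break towards the
lexicographically smallest site pair, making every result byte-reproducible.

## The shuffle null

Stacking energies are computed over dinucleotides, so a valid null must
preserve dinucleotide counts exactly, not just mononucleotide composition.
`dinuc_shuffle()` samples *uniformly* from the set of sequences with the
source's dinucleotide multiset and endpoints: the sequence is an Eulerian
path on the 4-vertex dinucleotide multigraph; a uniform arborescence into
the terminal vertex is drawn by rejection, each vertex's remaining out-edges
are permuted uniformly, and the path is walked. Uniformity (not merely
validity) matters because the extrinsic test treats the shuffles as an
i.i.d. null sample; it is verified empirically on enumerable cases
(chi-square against the exhaustive shuffle set).

## Per-genome statistics and their calibration

The extrinsic test pools all native pair energies (every head × every ncRNA)
into one sample and all shuffled-head pair energies into another, then
applies a one-tailed Mann-Whitney U test (native stochastically *greater*,
i.e. less stable). Pooling follows the original design; the alternative
(aggregating per shuffle replicate) was rejected because the scientific
claim compares energy *distributions*. Our `mann_whitney_u()` uses exact
permutation p-values when `nx·ny <= 400` and the pooled sample is tie-free,
and a midrank/tie-corrected normal approximation with continuity correction
otherwise — energies truncated at 0 create tie masses, so the tie correction
is not optional.

Two properties of the pooled design deserve honesty:

* **Matched nulls.** The shuffles of a head share its composition, so native
  and null samples are *matched*, and pair energies cluster within heads and
  within ncRNAs. The pooled U statistic therefore has *less* variance than
  the independent-samples formula assumes, and the per-genome p-values are
  conservative whenever several ncRNAs (strata) are pooled — we measure
  type-I rates of 1–3% at nominal 5% on no-effect genomes with 4–10 ncRNAs.
  Conservative, never anti-conservative: genome-scale avoider fractions are
  understated, not inflated.
* **Calibration standard.** When the independence assumptions hold — one
  ncRNA stratum, and heads that are dinucleotide-exchangeable with their own
  shuffles — the test is exactly calibrated. The calibration study in the
  acceptance suite therefore uses genomes with 40 heads, one 80-nt ncRNA and
  50 shuffles per head (1000 genomes), where the measured rejection rate is
  ~4–5% and the p-distribution passes a Kolmogorov–Smirnov uniformity check.

The intrinsic test is a two-tailed Mann-Whitney U on per-sequence G+C
fractions; its calibration run uses 30 heads and 20 ncRNAs per genome with
identical G+C targets (heads drawn i.i.d., since compositional heterogeneity
across sequences is exactly what this test consumes).

`density_difference_curve()` summarises a genome (or phylum) as
`density(native) - density(null)` on a common grid, with Silverman-bandwidth
Gaussian kernels per sample; positive lobes mark an excess of native
interactions at that energy. `phylum_summary()` aggregates avoider fractions
and `-log10(p)` quantiles per phylum and flags groups with fewer than 20
genomes, too small for a stable fraction.

## Positional profiles

`ncrna_window_profile()` slides a 10-nt window (step 1) along a ncRNA and
tests, per window, native-vs-shuffled head binding (one-tailed MWU,
`alpha = 0.001`). Windows are short and nearly unstructured, so the profile
uses the raw duplex energy by default. Window-level flags are reduced to
residues by "any covering window significant" (a `majority` rule is
available): the window test localises at best to window resolution, and the
permissive reduction favours sensitivity at a strict window alpha. For
multi-copy families (tRNAs) profiles are computed per sequence and projected
onto a user-supplied gapped alignment; the alignment itself is input, not
computed here.

`accessibility_association()` cross-tabulates avoided × contacted residues
(contacts from a 3.4 Å atom-distance table derived from a 3D structure,
consumed as TSV) and applies our exact hypergeometric Fisher test,
two-sided by default since the direction, though predicted (avoided ⇒
accessible), is the hypothesis under test. The reported odds ratio is the
odds of an avoided residue being accessible, `Inf`-capped.

## Expression statistics

`compute_cai()` is the classical geometric mean of relative adaptiveness
(zero counts smoothed to 0.5; single-codon amino acids and stops excluded);
the reference usage defaults to counts accumulated from the supplied coding
set. 5' structure uses `fold_mfe` on the first 37 nt; avoidance uses the
summed interaction energy of the first 21 nt against the ncRNA set. Protein
abundances are log-transformed before regression (zeros dropped with a
warning). `variance_partition()` reports per-feature, full-model and
full-minus-avoidance R²; `outlier_zscores()` z-transforms each metric over
all genes and tests the mean z of the 10 most and least productive genes
(by protein-per-mRNA ratio) against the standard normal background — a
pragmatic one-sample stand-in, since no exact procedure is canonical for
this display. `group_tests()` runs a Kruskal-Wallis test across construct
categories with pairwise one-tailed MWU + Holm as the post-hoc (a
studentized-range post-hoc exists but is under-specified for tied
fluorescence data; MWU + Holm is conservative and transparent).

## Synonymous mRNA design

`sample_synonymous()` draws codons uniformly per site — uniform, not
usage-weighted, because the designer wants the *extremes* of CAI, structure
and avoidance represented in the pool; a usage-weighted mode exists.
`select_extremes()` filters to the G+C band (0.468–0.480) and to heads with
exactly `round(0.48·21) = 10` G+C nucleotides — "identical 5' G+C of 0.48"
is not representable on a 21-nt head (10/21 ≈ 0.476), so the count is
matched instead — then greedily picks 2 × {min, max} constructs per metric
in the fixed order fold, CAI, avoidance (determinism), enforcing ≥ 100
substitutions between any two selections, and finally one optimal construct:
above the per-metric medians, best by lexicographic (CAI, fold, avoidance).
The default counts give 13 constructs. Scoring tolerates toy proteins
shorter than the 37-nt fold window by folding the full sequence with a
warning (a hard error would make the designer untestable on exhaustively
enumerable proteins).

`count_synonymous_variants()` multiplies codon degeneracies in exact
arbitrary-precision integers (a 239-aa protein has a ~112-digit count, far
beyond exact double range); `include_stop` adds the factor 3 for the stop
codon, and the package reports both conventions since published variant
counts rarely state which they use.

## The synthetic cohort: what it emulates, what it does not

All fixtures are generated, seeded, by `synth_genome()`,
`synth_expression()`, `synth_contacts()` and `synth_avoided_window()`:

* **Genomes.** ncRNAs are i.i.d. sequences at a target G+C (60–100 nt by
  default — tRNA-to-SRP scale). Heads are, by default, dinucleotide shuffles
  of one genome-level 21-nt template: within-genome compositional
  homogeneity (shared genomic G+C, shared codon bias) rendered exactly, with
  the convenient consequence that the no-effect null is exchangeable with
  the shuffle control. An `iid` mode provides per-head compositional
  heterogeneity; it is the right choice whenever the *intrinsic* test is
  part of the analysis, because on a compositionally degenerate bundle
  (every head sharing one G+C value) that test treats the identical heads
  as independent evidence and becomes anti-conservative —
  `intrinsic_avoidance_test()` warns when a class has zero within-class
  G+C variance.
* **Planted avoidance.** With `effect_delta > 0`, candidate heads are
  rejection-sampled until their mean interaction energy against the ncRNA
  set is at least `delta` kcal/mol *above* the genome's null mean — i.e.
  their interactions are at least `delta` weaker than composition predicts.
  Rejection sampling (not relabelling of energies) means the planted signal
  survives re-analysis under any energy mode. A draw budget (1e5) turns an
  infeasible `delta` into an error rather than a hang. The default fixture
  scale is 20 genomes × 50 heads × 10 ncRNAs × 50 shuffles.
* **Expression.** Real metrics are computed on generated coding sequences;
  log protein abundance is a planted linear function of the z-scaled metrics
  plus Gaussian noise, with the noise variance derived from a planned R²
  (`sigma² = var(signal)·(1-R²)/R²`). Planned quantities (full R², R² drop
  without avoidance) are computed from the noiseless signal and stored as
  ground truth, so recovery checks are not circular.
* **Contacts.** Residue contact flags copy or negate the avoidance flags
  with probability `1 - concordance` / `concordance`; concordance 1 is
  perfect anti-association (avoided ⇒ accessible), 0.5 independence.

What the generators do *not* emulate: phylogenetic correlation between
genomes, covariation structure in real ncRNAs, expression-level weighting of
ncRNA abundance, or measurement error models of mass spectrometry and
fluorescence. Passing tests therefore demonstrate the statistical machinery
and the planted-signal recovery, not the biological effect sizes of any real
genome — the per-genome test on real data is expected to behave
*conservatively*, as explained above.

## Problem sizes and numerical choices

Test and acceptance runs use sizes chosen to exercise each claim at
realistic power on a single CPU: 500 + 500 oracle instances (folds to 12 nt,
duplex pairs to 8 + 8 nt); 1000 shuffle sources; every Mann-Whitney size
pair to `nx + ny = 12` and every 2×2 table to `N = 30`; 1000 calibration
genomes per test; 40 planted-effect genomes; 30 expression cohorts of 200
genes; a fully enumerated 10-codon designer pool (6144 variants) plus a
4000-variant pool for a 239-aa protein. The 239-aa "GFP-scale" protein
shipped under `inst/extdata/` is a synthetic stand-in (its FASTA header says
so), used where a GFP-sized workload is needed without bundling third-party
sequence data.

Degenerate inputs are first-class: constant pooled samples return p = 1 with
a warning; all-zero energy matrices warn "no-interaction genome"; constant
expression yields NA correlations; zero mRNA abundances are excluded with a
warning; degenerate contingency margins are errors. Coordinates are 1-based
inclusive everywhere; sequences with ambiguity codes are skipped at input,
never repaired.

## Known limitations

* The energy scale is internally consistent but not comparable to published
  Turner-parameter outputs; absolute kcal/mol values should not be quoted
  against other software.
* The pooled per-genome MWU is conservative under multi-ncRNA pooling (see
  above); effect-size estimates (mean energy shifts) are unaffected.
* The ACCESS search is exact only up to the `max_site` cap and the duplex
  interior-loop cap.
* `run_*` drivers handle one genome per FASTA pair; cohort loops live in the
  `analysis/` scripts.
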