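---
title: "Proteomics-driven miRNA target screening with mirscreen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Proteomics-driven miRNA target screening with mirscreen}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mirscreen)
```

## The screening problem

A miRNA represses its targets post-transcriptionally, and part of that
repression (translational inhibition) is invisible to transcriptomics.
SILAC quantitative proteomics measures it directly: cells transfected with
the miRNA and with a non-targeting control are grown in isotopically
distinct media, mixed, and analyzed together, so each peptide carries a
light/heavy intensity pair whose ratio estimates the relative protein
abundance between conditions. `mirscreen` implements the downstream
analysis of such a screen end to end: peptide-to-protein ratio
aggregation, replicate merging and candidate filtering, 3'UTR binding-site
evaluation, target-cluster mining, and isoform-divergence analysis.

Because raw mass-spectrometry data are neither required nor practical for
validating this logic, the package ships a synthetic-data generator that
emulates the peptide tables of a two-replicate screen with known ground
truth; every pipeline stage is exercised against that truth or against an
independent oracle in the test suite.

## Quantification model

For one protein in one replicate, each quantifiable peptide $i$ (both
channel areas positive) contributes a log-ratio
$r_i = \log_2(\text{treated}_i / \text{control}_i)$. The primary estimate
is the mean of the $r_i$ after one outlier-rejection pass with Dixon's Q
test ($\alpha = 0.05$, $3 \le n \le 30$, most extreme value only — a
single pass, mirroring classical SILAC ratio estimators). The peptide
noise variance is estimated from the within-protein scatter, which is
shared by all peptides of the protein, so inverse-variance weighting
reduces to the unweighted mean with standard error
$\mathrm{sd}(r)/\sqrt{n}$. A companion estimate, the log2 ratio of summed
areas $\log_2(\sum_i \text{treated}_i / \sum_i \text{control}_i)$, plays
the role of a second, independent quantification algorithm; the two agree
exactly whenever all peptides share one ratio.

A protein ratio is *concordant* when the two estimators diverge less than
twofold on the linear scale, or when both are > 3.0 or both < 0.33; only
concordant proteins enter the screen.

Significance is assessed per replicate against the replicate's own
protein-ratio population (replicates come from distinct runs): the
two-sided tail probability of the protein's log2 fold change under a
normal model with robust center (median) and spread (MAD × 1.4826).
This robust-normal model is a declared stand-in for the original
ASAPRatio significance model (a fit of the normalized ratio histogram),
which is not fully specified in the literature we follow; it preserves
the properties the screen relies on — p = 1 at the population center,
symmetry, monotone decrease with distance — and yields approximately
uniform null p-values, which the false-positive-rate test checks.
Populations with MAD = 0 are refused with a pointer to the `spread = "sd"`
fallback rather than silently producing infinite z-scores.

## Replicate merging and the candidate filter

Per-replicate p-values $p_1, p_2$ are merged with Fisher's method:
$x = -2(\ln p_1 + \ln p_2)$ is $\chi^2_4$ under the null, and the merged
p-value has the closed form $e^{-x/2}(1 + x/2)$. Stouffer's method is
available as a configuration, but Fisher is the default combination rule.
A protein passes the screen when:

1. merged p-value **< 0.1** (strict);
2. abundance decreases by **more than 25%** in *both* replicates, i.e.
   linear fold change strictly below 0.75
   ($\log_2 \text{FC} < \log_2 0.75 \approx -0.415$);
3. both replicate fold changes are negative (implied by 2, reported as its
   own flag).

Boundary semantics are literal: "less than 0.1" and "more than 25%" are
strict inequalities. Under this reading, replicate fold changes of −0.45
and −0.44 (decreases of 26.8% and 26.3%) pass, which the bundled
candidate-table fixture exercises. When the two quantification algorithms
disagree within the concordance window, the filter is evaluated on the
mean-based (primary) estimate, whose values the candidate tables carry.
The screen applies no multiplicity correction: the published procedure it
reproduces uses a fixed merged-p threshold, and the per-criterion flags
make it easy to layer one on top if desired.

A manual peptide-level inspection step in the original procedure is not
formalizable; in its place the per-protein output retains `n_peptides`,
`n_excluded` and `n_rejected` diagnostics for export.

## Binding-site scanning and scoring

The scanner finds Watson–Crick matches of the miRNA seed (mature
positions 2–7) on the UTR sense strand and classifies them canonically:
6mer (core only), 7mer-m8 (core plus pairing at position 8), 7mer-A1
(core plus an adenine opposite position 1), 8mer (both). Coordinates are
1-based inclusive over the full matched span; overlapping matches of one
miRNA are merged to the highest class (ties to the leftmost). `N` never
matches; G:U wobble pairing is off by default and available as a flag.
This seed taxonomy is a deliberate surrogate for alignment-plus-energy
site finders (e.g. miRanda), whose web-service parameters are not
reproducible offline; the scanner is instead verified exactly against a
brute-force substring-enumeration oracle.

Site scores are either (a) attached verbatim from an external prediction
table (the route used for published mirSVR scores, which this package
does not attempt to re-derive — regression scoring is out of scope), or
(b) a deterministic surrogate: a base weight per class
(8mer −0.35 < 7mer-m8 −0.20 < 7mer-A1 −0.12 < 6mer −0.03) scaled by
$0.5 + \text{AU fraction}$ of the 30-nt flanks, reflecting the
accessibility benefit of AU-rich context. Surrogate scores are only meant
to induce a realistic ordering; their absolute values carry no meaning.
Per-UTR combined scores are plain sums over sites (0 for no sites),
matching how per-site scores are combined in public miRNA-target
databases.

Consensus votes count, for each gene, how many of the supplied predictor
gene lists contain it (reported as `n/k`), reproducing the
"predicted by n out of k algorithms" triage.

## Target-cluster mining

Given an interaction table (miRNA, gene, combined per-UTR score) and a
query gene set, the cluster of the set is the exact intersection of the
per-gene binder sets. Cluster miRNAs are ranked by their summed score
across the cluster genes, most negative first, ties broken
lexicographically. Genes absent from the table empty the intersection
with a warning — silently dropping them would overstate clusters. Cluster
discovery is query-driven; enumerating all maximal biclusters is
deliberately out of scope. The bundled interaction table is a
database-content emulation built to the published per-gene coverage
marginals and cluster structure (14 miRNAs over the four-gene cluster,
including the five miR-200 family members, with miR-590-3p strongest at a
summed score of −9.77); filler miRNA names in it are systematic
(`hsa-miR-sNNN`) and globally unique so that the four-gene intersection
is exactly the intended 14.

## Global alignment for isoform divergence

`global_align()` is a Gotoh three-state dynamic program with affine gaps
under BLOSUM62 (protein) or a +5/−4 full-DNA matrix, defaults gap open
10.0 and extend 0.5 with a gap of length $L$ costing
$\text{open} + \text{ext}\,(L-1)$, and end gaps unpenalized — the default
parameterization of the EMBOSS Needle tool whose behaviour it mirrors.
Identity and similarity are fractions of the full alignment length
(including gap columns); "similar" counts residue pairs with positive
substitution score, identities included. Report rounding is half-up to
two decimals; full precision is retained on the result object. The
implementation is in C++ for speed and is checked in the tests against an
independent plain-R DP oracle (exhaustively over all short 4-letter pairs
up to length 2 plus a large fixed-seed sample up to length 8, in both
end-gap modes) and by re-scoring every emitted alignment under the gap
model.

The repository bundles *synthetic* isoform stand-ins
(`isoforms_synthetic.fasta`) for demonstrating `divergence_report()`;
they are random sequences, clearly labelled, and deliberately not
calibrated to any published identity value. Divergence numbers computed
on them describe only the stand-ins; reproducing published isoform
divergences requires supplying the corresponding UniProt isoform-1
sequences in the same FASTA layout.

## What the synthetic generator emulates — and what it does not

`simulate_silac_experiment()` draws, per protein: a log-normal base
abundance (meanlog log(1e6), sdlog 1); independent Bernoulli
identification per replicate (`detect_prob`), the simplest mechanism
producing the partial replicate overlap intrinsic to shotgun proteomics;
a number of peptides uniform in `peptides_per_protein`; per-peptide
log-normal ionization spread (sdlog 0.5) and Gaussian log2-ratio noise
(`noise_sd_log2`). True targets (fraction `frac_true_targets`) receive a
uniform log2 effect from `effect_range_log2`; all other effects are
exactly 0, so zero-noise null simulations give ratios of exactly 1.

Defaults were calibrated once from the identification counts of the
two-replicate screen the package reproduces: a shared/per-replicate ratio
of ~0.86 gives `detect_prob = 0.86`, and `n_proteins_total = 2350` then
yields ~2,020 identified proteins per replicate and ~1,730 shared. The
default effect interval \[−1.6, −0.4\] spans the confirmed candidate
effect sizes. The channel assignment of the treated cells is not
documented for the original experiment, so it is a configuration
(`treated_channel`, default `"heavy"`) rather than a guess baked into the
model.

Not emulated: spectrum-level structure (m/z, retention time, charge
states), identification FDR and decoys, shared/razor peptides,
missing-value mechanisms correlated with abundance, and
between-replicate batch effects. Passing tests therefore demonstrate the
correctness of the aggregation, filtering, scanning and mining logic
under a clean error model — not robustness to every pathology of real
mass-spectrometry data.

`simulate_utr_database()` synthesizes uniform-composition DNA UTRs and
implants exact seed-complementary sites (classes sampled from 8mer,
7mer-m8, 7mer-A1), forcing the flanking bases not to extend the match so
the implanted class is recovered exactly. Background sequence can and
does contain chance seed matches; ground truth records implants only, and
scanner correctness is asserted against the enumeration oracle, not
against a false-positive rate claim.

## Problem sizes and determinism

All randomness flows through a single seed per generator invocation
(plus fixed offsets separating the peptide and UTR streams), making every
output byte-reproducible. The test suite runs the screen at 2,000
proteins (recall/precision/bias of the full pipeline at 1% true targets,
effect −1.0, noise 0.3, 10 peptides/protein), the scanner oracle at 200
random UTRs up to 500 nt, the cluster oracle at 600-row random tables,
and the aligner oracle at several hundred short pairs — sizes chosen to
give stable statistics at interactive runtimes. Recall is defined over
true targets identified in both replicates, since the screen by design
evaluates only shared proteins.

## Known limitations

* The significance model is a robust-normal approximation, not the
  original ASAPRatio histogram fit; absolute p-values will differ from
  that tool even where rankings agree.
* Surrogate site scores are ordinal stand-ins, not mirSVR values; any
  quantitative use of scores should go through an external score table.
* The seed-match scanner does not model 3' supplementary pairing,
  thermodynamics, or conservation.
* The cluster miner answers set-intersection queries; it does not search
  for clusters de novo.
* Bundled interaction and isoform fixtures are emulations for desk-scale
  testing, not database exports.
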