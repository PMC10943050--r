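---
title: "From somatic mutation catalogs to five-year-survival prediction: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From somatic mutation catalogs to five-year-survival prediction: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sigcca)
```

This vignette is the package's own account of the science it implements:
the models, the tunable parameters and their defaults, the numerical
choices, and the places where the design was genuinely open and a decision
had to be made. Nothing stated here goes beyond what the package's tests
and acceptance script themselves compute.

## The 96-context catalog

A somatic single-base substitution is classified by its substitution type
and the bases immediately 5′ and 3′ of the mutated position. Because a
substitution on one strand is the same event as its reverse complement on
the other, classes are collapsed onto the pyrimidine strand: a purine
reference (A or G) is reverse-complemented together with both flanks before
labelling. That yields 6 substitution types (C>A, C>G, C>T, T>A, T>C, T>G)
× 4 5′ flanks × 4 3′ flanks = 96 classes, written `"A[C>T]G"`, in the fixed
COSMIC column order (type, then 5′ flank, then 3′ flank). The order is
identical across all catalogs the package writes, so output files are
byte-comparable.

Conventions worth stating explicitly:

* Coordinates are 1-based inclusive (MAF convention). Strand fields in the
  input are ignored; collapsing is done by classification only.
* Indel records contribute to per-sample mutation totals (used for
  hypermutation flagging) but never to the 96-class matrix.
* SBS records with non-ACGT bases or multi-base alleles (N flanks, MNVs,
  multi-allelic rows) are skipped with a warning and a returned skip count,
  never decomposed and never fatal.
* Flanking bases come from explicit `flank5`/`flank3` columns, from a
  `context`/`ref_context` column (either `"X[R>Y]Z"` notation or an
  odd-length sequence centred on the variant), or optionally from an
  indexed genome FASTA. No reference download is ever required.
* Hypermutation is a configurable burden threshold, default total
  mutations > 1000 per sample — the usual exome-scale convention. The
  boundary is strict (`>`), and raising the threshold can only shrink the
  flagged set.

## Signature extraction by NMF

The catalog matrix $V$ (96 × N, classes × samples) is factorised as
$V \approx WH$ with $W \ge 0$ (96 × K profiles) and $H \ge 0$ (K × N
exposures), minimising the generalized Kullback–Leibler divergence

$$D(V \| WH) = \sum_{ij} \left( V_{ij} \log \frac{V_{ij}}{(WH)_{ij}}
  - V_{ij} + (WH)_{ij} \right)$$

by the standard multiplicative updates. KL is the natural objective for
count data under a Poisson sampling model, which is how mutation catalogs
arise; a Frobenius (squared-error) objective is available behind
`objective = "frobenius"`.

Numerical choices:

* **Initialisation**: strictly positive uniform random entries (so no
  multiplicative update can be trapped at an accidental zero), 20 restarts
  by default, best restart chosen by final objective with ties broken by
  restart index.
* **Convergence**: stop when the relative objective change over 10
  iterations falls below `tol = 1e-6`, capped at `max_iter = 2000`.
* **Normalisation**: after the winning restart, each column of $W$ is
  scaled to sum to 1 (a proper distribution over the 96 classes) with the
  scale absorbed into $H$.
* **Exposure refit**: $H$ is then refit per sample with $W$ held fixed
  (H-only multiplicative updates on the same objective). At a KL stationary
  point with column-stochastic $W$, each sample's activities sum to its
  mutation count, which is what makes "exposure" readable as *attributed
  mutations*; the tests verify this conservation to 1e-6 relative.
* **Ordering and naming**: signatures are sorted by descending total
  activity and named `S1…SK` until matched against a reference panel.
* Deterministic given `seed`: the restart schedule is drawn from one seeded
  stream, and the caller's RNG state is restored afterwards.

### Choosing K

The number of active mutational processes is unknown, so `select_rank()`
scans a grid and reports, per K, the best-restart reconstruction error and
a *stability* score: the mean cosine similarity between each restart's
profiles and the best restart's profiles after greedy one-to-one matching.
Stability near 1 means the restarts agree on the solution; it drops sharply
once K exceeds the number of processes the data supports. The chosen K is
the smallest K (below the top of the grid) whose stability is at least
`stability_floor = 0.9` and whose relative error improvement moving to K+1
falls below `improvement_ratio = 0.1` — a conventional elbow rule; if no K
qualifies, the most stable K is returned. Both cutoffs are exposed as
arguments, and the full diagnostics table is always returned so the user
can overrule the rule. On a three-process synthetic catalog the diagnostics
show exactly the expected pattern (stability ≈ 1.0 through K = 3, dropping
to ≈ 0.9 at K = 4, with the error elbow at 3), and the tests pin this down.

Greedy matching (repeatedly pairing the highest remaining cosine) rather
than full Hungarian assignment is deliberate: at the K ≤ 15 scales relevant
here the two agree except in pathological ties, and the greedy matcher has
no dependency.

## Naming against a reference panel

Each extracted profile is assigned the reference signature with the highest
cosine similarity; the assigned name is the reference name plus a trailing
asterisk (`SBS44*`), marking a de-novo extraction matched to that
reference. Matches below `min_cosine = 0.80` keep the provisional name and
are flagged *novel* — the default sits just below the weakest match one
would still reasonably accept (published gastric-cancer extractions accept
matches down to ≈ 0.82). Exact ties break lexicographically (logged), and
two extractions hitting the same reference are both reported, flagged as a
collision, rather than silently reassigned. Matching is invariant to panel
column order and to positive rescaling of any profile, and raising
`min_cosine` can only convert named matches to novel, never the reverse.

The package bundles `make_fixture_panel()`: eight deterministic synthetic
profiles carrying COSMIC-style names whose shapes are loosely evocative of
the processes those names denote (CpG C>T spikes for "SBS1", a `C[T>G]T`
spike for "SBS17b", broad C>A for "SBS18", a C>T + T>C mix for "SBS44").
They are synthetic stand-ins — not the published profiles — with all
pairwise cosines below 0.5 so that matching in tests and examples is
unambiguous. Real analyses should supply a genuine reference panel TSV via
`read_ref_panel()`.

## Cumulative contribution abundance

Given a fit, the probability that signature $k$ generated a mutation of
class $c$ in sample $j$ is the normalised product of profile and exposure:

$$P(k \mid c, j) = \frac{W_{ck} H_{kj}}{\sum_{k'} W_{ck'} H_{k'j}}.$$

CCA(sample, gene, signature) is the sum of these posteriors over the
sample's gene-annotated SBS mutations in that gene: the expected number of
the gene's mutations attributable to the signature, *cumulative* across all
of the gene's mutations. This summed-posterior definition was an open
design point — the score could conceivably be normalised per gene length or
per sample burden — and the package's position is: "abundance" reads as a
count, so the default is the raw cumulative posterior mass, with a
per-sample normalised variant behind `normalize = TRUE` and the choice
recorded in the output object. Gene assignment is taken verbatim from the
input's gene column; no transcript-model re-annotation is attempted.

Two consequences are load-bearing and tested: total CCA mass per sample
equals its gene-annotated SBS count (posteriors sum to 1 per mutation), and
on small cohorts the fast aggregation path agrees cell-by-cell with a
brute-force loop over every (mutation, signature) pair. Mutations whose
candidate products are all zero fall back to a uniform posterior over the
sample's active signatures, with a warning — preferring an explicit,
flagged convention over silent NaNs.

## Survival grouping and exposure stratification

Samples partition into four groups: G1, survival strictly greater than
60 months (five years), regardless of vital status; G2, under five years
and deceased; G3, under five years and alive at last follow-up
(right-censored); G4, missing follow-up or status. "Five years" is 60.0
months with a strict inequality, so a survival time of exactly 60 months
falls in G2/G3 by status — the boundary convention is logged in the
documentation rather than left implicit.

`stratify_by_exposure()` splits samples at a relative-exposure threshold
(default 0.2: more than 20 % of the sample's mutations attributed to the
signature; strictly greater, so exactly-at-threshold samples are *low*),
excludes G4, fits Kaplan–Meier curves per arm and compares them with a
two-sided log-rank test. An absolute-count threshold is available behind
`absolute = TRUE`. Arms with fewer than two samples yield a result object
with the test explicitly flagged undefined instead of a spurious p-value.
The KM estimate and log-rank test are delegated to the survival package;
the tests check the estimator against the empirical survival function on
uncensored data and the statistic against a hand-rolled risk-set
computation, and a 1000-replicate null simulation confirms the stratified
test holds its 5 % level (rejection rate within [0.03, 0.07]).

## The FYSR prediction procedure

The five-year-survival model classifies G1 against G2 on CCA features
(`"GENE|SIG"` columns; the combined two-signature model simply unions both
signatures' columns in one matrix). G3 and G4 are excluded from training —
their five-year outcome is undefined — though G3 can be scored at predict
time. Training repeats, for `n_rounds` (default 100):

1. draw 95 % of cases without replacement, stratified by class so both
   classes survive the draw;
2. fit a probability random forest (500 trees, unlimited depth, √p
   features per split — the field's standard defaults, recorded in the
   model object);
3. compute the round's *training AUC* and, if it exceeds the gate
   (default 0.9), add the round's top-importance features to a tally.

Features tallied in more than `freq_gate` (default 50 %) of the
gate-passing rounds form the biomarker panel, and the final forest is refit
on all cases restricted to that panel. Three sub-choices deserve comment:

* **The training AUC is computed from out-of-bag predictions** on the
  round's subsample. In-sample random-forest predictions are near-perfect
  by construction and would pass any gate vacuously; the OOB estimate is
  the only training-side quantity for which the gate is informative, and it
  behaves correctly under the null — with permuted labels essentially no
  round passes, which the tests assert.
* **"Top-importance" per round** defaults to impurity importance above the
  round's mean importance; a fixed top-k alternative is available. The
  above-mean rule adapts to how concentrated the signal is without a tuned
  constant.
* **The frequency denominator is the number of gate-passing rounds** (the
  screened models), not all rounds. Screening first and then asking how
  often a feature recurs among the accepted models is the reading that
  keeps selection meaningful when the gate is selective.

Selection is anti-monotone in `freq_gate` (raising it never grows the
panel), the whole procedure is byte-reproducible given seed and config, and
the degenerate configuration (one round, full subsample, zero gate)
collapses to a single forest on all data.

ROC/AUC uses the trapezoidal rule over the empirical ROC — equal, with the
half-weight tie convention, to the Mann–Whitney pair-counting statistic, an
identity the tests verify exactly on all-distinct-score instances. The 95 %
confidence interval is a stratified bootstrap (positives and negatives
resampled separately; 2000 replicates; percentile interval) by default,
with DeLong's asymptotic interval behind `ci_method = "delong"`; bounds are
clipped to [0, 1], so a printed upper bound of 1 is possible.

## The synthetic cohort generator

`simulate_cohort()` emulates the structure of a pooled somatic cohort: per
sample, an exposure vector from a Dirichlet distribution; a Poisson
mutation burden (mean 300 by default, exome scale), with a hypermutator
subpopulation (default 7 % of samples at 20× burden, mirroring the roughly
7 % hypermutated fraction reported in gastric cohorts); per mutation, a
generating signature drawn by exposure, a 96-class drawn from that
signature's profile, and a gene from a mutability panel. SBS records are
emitted on a random strand, so the classifier's pyrimidine collapsing is
genuinely exercised, and about 10 % of records are indels. Survival is
exponential with log hazard linear in the true relative exposures,
censored by an independent uniform follow-up horizon (120 months), with a
configurable fraction of samples losing their clinical row to populate G4.
The ground truth — exposures, per-mutation signature identities, carrier
states, hazards — is returned alongside, and the emitted tables round-trip
through the package's own readers.

Planting gene-level signal uses `gene_bias`: within a *carrier*
subpopulation (default device: `carrier_fraction = 0.5`), a gene's weight
is multiplied (×20 in the shipped configuration) for mutations generated by
one signature — the caricature of a repair-deficient subgroup concentrating
a signature's mutations in particular genes. With
`pair_effect_scale = "carrier"`, survival attaches to the carrier state
itself and the planted (gene, signature) counts are its mutational readout.
This is the shipped planted-biomarker study design: three carrier states
(two on the SBS44-like process with opposing effects, one on the
SBS18-like) with per-carrier log-hazard effects of ∓6 and +5, exposures at
Dirichlet(8) so the cohort is moderately heterogeneous but exposure alone
carries little outcome information, and a baseline hazard of
(log 2/60)·e^−2.5 per month placing the five-year boundary between the
carrier strata. Under those conditions the full pipeline — simulate,
catalog, extract, match, attribute, train at the published subsampling
settings — recovers all three planted biomarkers while rejecting at least
90 % of 30 decoy features.

What the generator does *not* emulate, and hence what passing tests do not
show: real genome coordinates or gene lengths (gene weights are abstract
mutability, so CCA's lack of length normalisation is untested against
length confounding); covariate structure of mutation rate (replication
timing, expression); non-exponential survival shapes or informative
censoring; inter-cohort batch structure. Results on synthetic cohorts
demonstrate correctness of the machinery, not clinical performance.

## Problem sizes

The shipped tests and the acceptance script run, by design, at desk scale:
profile-recovery cohorts of 100 samples × ~300 mutations with 20 NMF
restarts; the planted-biomarker cohort at 200 samples with 100 subsampling
rounds; the type-I simulation at 1000 replicates of n = 200; brute-force
oracles on cohorts of ≤ 5 samples (CCA) and ≤ 50 scores (AUC). These sizes
make every property checkable in seconds to a couple of minutes on one CPU
while staying large enough for the statistical assertions (cosine ≥ 0.95
recovery, exposure correlation ≥ 0.9, rejection rate within [0.03, 0.07])
to be meaningful.

## Known limitations

* CCA is unnormalised by gene length or coverage; in real exomes long
  genes accumulate mass for purely structural reasons. The normalised
  variant mitigates burden confounding only.
* Signature attribution assumes the fitted W and H are correct; attribution
  uncertainty is not propagated into CCA or the downstream classifier.
* The rank-selection rule is a heuristic elbow; for real cohorts the
  diagnostics table should be inspected rather than trusted blindly.
* The forest's importance-based selection inherits impurity importance's
  bias toward high-variance features; the shipped configuration keeps
  features on a common count scale, which softens but does not remove this.
* Indel signatures, doublet substitutions, signature decomposition into
  reference combinations, and Cox-type covariate modelling are out of
  scope.
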