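# sigcca

Mutational-signature analysis and five-year-survival prediction for cancer
cohorts, built around gene-level **cumulative contribution abundance (CCA)**
scores.

Somatic single-base substitutions (SBS) carry the imprint of the mutational
processes that generated them. Collapsed onto the pyrimidine strand and
classified by their flanking bases, they fall into 96 trinucleotide-context
classes; a cohort becomes a catalog matrix **V** (samples × 96) that
factorises as **V ≈ W·H**, where the columns of **W** are signature
profiles (probability distributions over the 96 classes) and **H** holds
per-sample exposures (attributed mutation counts). Signatures extracted de
novo are named by cosine similarity against a COSMIC-style reference panel
(an extraction matching SBS44 is reported as `SBS44*`).

Exposures alone ignore *where* the mutations land. The CCA score resolves
this: for each mutation, the posterior probability that signature *k*
generated it is

    P(k | class c, sample j) ∝ W[c, k] · H[k, j]

and CCA(sample, gene, signature) is the summed posterior mass over the
sample's mutations in that gene — the expected number of the gene's
mutations attributable to the signature. These (gene, signature) scores are
the features of a five-year-survival (FYSR) classifier: cases surviving
beyond five years (G1) against cases deceased within five years (G2),
learned by a random forest under repeated 95 % subsampling with a
training-AUC gate and frequency-based biomarker selection, and evaluated by
ROC/AUC with bootstrap confidence intervals. Kaplan–Meier stratification of
survival by a signature's relative exposure (e.g. "more than 20 % of a
tumour's mutations attributed to `SBS44*`") is included, as is a fully
specified synthetic-cohort generator so that every stage is testable with
known ground truth and no external downloads.

Intended users: cancer-genomics researchers working with MAF-style somatic
mutation tables and clinical follow-up, and methodologists who want a
transparent, seedable re-implementation of a signature-driven prognosis
pipeline.

## Worked example

```r
library(sigcca)

# simulate a 100-sample cohort from three known mutational processes;
# high SBS44-like exposure is protective (log-hazard -2 per unit fraction)
cohort <- simulate_cohort(sim_config(n_samples = 100, mean_mutations = 300,
                                     beta = c(SBS1 = 0, SBS18 = 0,
                                              SBS44 = -2),
                                     seed = 42))

# 96-context catalog
catalog <- build_catalog(cohort$mutations)
catalog
#> 96-context SBS catalog: 100 sample(s), 83646 substitutions
#> substitution class proportions:
#>   C>A   C>G   C>T   T>A   T>C   T>G
#> 0.304 0.017 0.499 0.018 0.144 0.018

# extract three signatures and name them against the bundled panel
fit <- extract_signatures(catalog, rank = 3, n_restarts = 20, seed = 42)
matches <- match_panel(fit, make_fixture_panel())
matches
#>   extracted_id reference_name    cosine assigned_name novel collision
#> 1           S1           SBS1 0.9998569         SBS1* FALSE     FALSE
#> 2           S2          SBS18 0.9955750        SBS18* FALSE     FALSE
#> 3           S3          SBS44 0.9795580        SBS44* FALSE     FALSE

# gene-level cumulative contribution abundance
fit <- apply_matches(fit, matches)
att <- attribute_mutations(cohort$mutations, fit)
cca <- compute_cca(att, signatures = c("SBS44*", "SBS18*"))
head(cca, 3)
#>   sample   gene signature      cca
#> 1 SIM001 GENE01    SBS18* 1.668344
#> 2 SIM001 GENE01    SBS44* 2.949228
#> 3 SIM001 GENE02    SBS18* 2.089272

# survival stratified at 20% relative exposure
km <- stratify_by_exposure(fit$relative["SBS44*", ], cohort$clinical,
                           threshold = 0.2)
km
#> exposure stratification at fraction > 0.2
#> arms: high n=61, low n=31
#> log-rank chi-square = 4.020, p = 0.04496
#> median survival (months): low = 41.06878 , high = 67.1494
```

The match table reads: each de-novo signature's best reference and the
cosine similarity of the two profiles (values near 1 mean the extraction
reproduced the reference shape). The CCA rows give, per sample, the
expected number of mutations in each gene attributable to each selected
signature. The stratification output shows that tumours with more than
20 % `SBS44*` exposure survive longer (median 67 vs 41 months; two-sided
log-rank p = 0.045), matching the protective effect built into the
simulation.

For FYSR model training, `assign_groups()` labels samples G1–G4 from
follow-up data, `cca_feature_matrix()` produces the samples × `"GENE|SIG"`
matrix, and `fysr()` runs the subsampling/selection procedure
(`?fysr` for the full control set). A thin command-line front end is
installed as `exec/sigcca` with subcommands `catalog`, `extract`, `match`,
`cca`, `km` and `synth`.

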