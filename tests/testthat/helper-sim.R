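# shared fixtures and independent oracles, built in code at test time

# minimal SBS record constructor
sbs_rec <- function(sample, ref, alt, f5, f3, gene = "") {
  data.frame(sample = sample, chrom = "chr1",
             pos = seq_along(sample) + 100L,
             ref = ref, alt = alt, gene = gene,
             flank5 = f5, flank3 = f3, variant_class = "SBS",
             stringsAsFactors = FALSE)
}

indel_rec <- function(sample, gene = "") {
  data.frame(sample = sample, chrom = "chr1",
             pos = seq_along(sample) + 500L,
             ref = "A", alt = "AT", gene = gene,
             flank5 = NA_character_, flank3 = NA_character_,
             variant_class = "INDEL", stringsAsFactors = FALSE)
}

# the planted-biomarker study cohort: three carrier-state biomarkers
# (two on the SBS44-like process, one on the SBS18-like) drive survival;
# their mutational readout is a 20x concentration of the signature's
# mutations in the biomarker gene within carriers
planted_cohort_config <- function(seed) {
  w <- 0.9^(0:39)
  g <- sprintf("GENE%02d", 1:40)
  w[c(20, 25, 30)] <- w[15]
  genes <- data.frame(gene = g, weight = w / sum(w),
                      stringsAsFactors = FALSE)
  pairs <- data.frame(gene = c("GENE20", "GENE25", "GENE30"),
                      signature = c("SBS44", "SBS44", "SBS18"),
                      effect = c(-6, 6, 5), stringsAsFactors = FALSE)
  bias <- data.frame(gene = pairs$gene, signature = pairs$signature,
                     bias = 20, carrier_fraction = 0.5,
                     stringsAsFactors = FALSE)
  sim_config(n_samples = 200, mean_mutations = 300,
             exposure_alpha = rep(8, 3), hypermut_fraction = 0,
             missing_clinical_fraction = 0.05, genes = genes,
             baseline_rate = (log(2) / 60) * exp(-2.5),
             gene_bias = bias, pair_effects = pairs,
             pair_effect_scale = "carrier", seed = seed)
}

# run the full pipeline on the planted cohort up to the labelled CCA
# feature matrix restricted to the 3 planted + 30 decoy features
planted_feature_set <- function(seed, nmf_seed = 5) {
  cfg <- planted_cohort_config(seed)
  sim <- simulate_cohort(cfg)
  ct <- build_catalog(sim$mutations)
  fit <- extract_signatures(ct, rank = 3, n_restarts = 20, seed = nmf_seed)
  mm <- match_panel(fit, make_fixture_panel())
  colnames(fit$signatures) <- mm$assigned_name
  rownames(fit$exposures) <- mm$assigned_name
  att <- attribute_mutations(sim$mutations, fit)
  cc <- compute_cca(att, signatures = c("SBS44*", "SBS18*"))
  planted <- paste(cfg$pair_effects$gene,
                   paste0(cfg$pair_effects$signature, "*"), sep = "|")
  Xall <- cca_feature_matrix(cc)
  decoys <- setdiff(colnames(Xall), planted)[1:30]
  X <- Xall[, c(planted, decoys)]
  grp <- assign_groups(sim$clinical)
  lab <- grp$group[match(rownames(X), grp$sample)]
  keep <- lab %in% c("G1", "G2")
  list(x = X[keep, , drop = FALSE],
       y = droplevels(factor(lab[keep])),
       planted = planted, sim = sim)
}

# O(n_pos * n_neg) Mann-Whitney pair-counting AUC (independent oracle)
auc_pair_counting <- function(scores, is_pos) {
  pos <- scores[is_pos]
  neg <- scores[!is_pos]
  total <- 0
  for (p in pos) total <- total + sum(p > neg) + 0.5 * sum(p == neg)
  total / (length(pos) * length(neg))
}

# brute-force two-arm log-rank chi-square from risk-set tables
logrank_brute <- function(time, status, arm) {
  times <- sort(unique(time[status == 1]))
  O <- E <- V <- 0
  for (t in times) {
    at_risk <- time >= t
    n <- sum(at_risk)
    n1 <- sum(at_risk & arm)
    d <- sum(time == t & status == 1)
    d1 <- sum(time == t & status == 1 & arm)
    O <- O + d1
    E <- E + n1 * d / n
    if (n > 1) V <- V + d * (n - d) * n1 * (n - n1) / (n^2 * (n - 1))
  }
  (O - E)^2 / V
}
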