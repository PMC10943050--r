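# a tiny hand-built fit: two signatures with known profiles and exposures
toy_fit <- function() {
  labels <- sbs_class_labels()
  W <- matrix(1 / 96, 96, 2, dimnames = list(labels, c("sigA", "sigB")))
  W[, 1] <- 0
  W["A[C>A]A", 1] <- 0.2
  W["A[C>T]T", 1] <- 0.8
  W[, 2] <- 0
  W["A[C>A]A", 2] <- 0.1
  W["A[C>T]T", 2] <- 0.9
  H <- matrix(c(0.5, 0.5), 2, 1, dimnames = list(c("sigA", "sigB"), "s1"))
  list(signatures = W, exposures = H)
}

test_that("per-mutation posteriors normalize the exposure-profile products", {
  recs <- sbs_rec("s1", "C", "A", "A", "A", gene = "TP53")
  att <- attribute_mutations(recs, toy_fit())
  # products (0.5*0.2, 0.5*0.1) -> posterior (2/3, 1/3)
  expect_equal(att$sigA, 2 / 3, tolerance = 1e-12)
  expect_equal(att$sigB, 1 / 3, tolerance = 1e-12)
})

test_that("a single active signature takes the whole posterior", {
  fit <- toy_fit()
  fit$exposures["sigB", ] <- 0
  att <- attribute_mutations(sbs_rec("s1", "C", "A", "A", "A", "TP53"), fit)
  expect_equal(att$sigA, 1)
  expect_equal(att$sigB, 0)
})

test_that("posteriors sum to one for every mutation in a cohort", {
  sim <- simulate_cohort(sim_config(n_samples = 15, mean_mutations = 120,
                                    seed = 19))
  fit <- extract_signatures(build_catalog(sim$mutations), rank = 3,
                            n_restarts = 5, seed = 3)
  att <- attribute_mutations(sim$mutations, fit)
  post <- as.matrix(att[, rownames(fit$exposures)])
  expect_equal(unname(rowSums(post)), rep(1, nrow(post)), tolerance = 1e-9)
})

test_that("CCA accumulates posteriors per sample, gene and signature", {
  # two TP53 mutations with posteriors (0.6, 0.4) and (0.2, 0.8)
  att <- data.frame(sample = "s1", gene = "TP53",
                    class = c("A[C>A]A", "A[C>T]T"),
                    sigA = c(0.6, 0.2), sigB = c(0.4, 0.8),
                    stringsAsFactors = FALSE)
  cc <- compute_cca(att)
  expect_equal(cc$cca[cc$gene == "TP53" & cc$signature == "sigA"], 0.8)
  expect_equal(cc$cca[cc$gene == "TP53" & cc$signature == "sigB"], 1.2)
  expect_error(compute_cca(att, signatures = "sigZ"), "sigZ")
})

test_that("CCA mass is conserved and matches a brute-force loop", {
  sim <- simulate_cohort(sim_config(n_samples = 5, mean_mutations = 60,
                                    seed = 23))
  fit <- extract_signatures(build_catalog(sim$mutations), rank = 3,
                            n_restarts = 5, seed = 6)
  att <- attribute_mutations(sim$mutations, fit)
  cc <- compute_cca(att)

  # conservation: total CCA per sample = gene-annotated SBS count
  tot <- tapply(cc$cca, cc$sample, sum)
  sbs <- sim$mutations[sim$mutations$variant_class == "SBS" &
                         sim$mutations$gene != "", ]
  cnt <- table(sbs$sample)
  expect_equal(as.numeric(tot[names(cnt)]), as.numeric(cnt),
               tolerance = 1e-6)

  # brute force over every (mutation, signature) pair
  sigs <- rownames(fit$exposures)
  for (s in unique(cc$sample)) {
    for (g in unique(cc$gene[cc$sample == s])) {
      rows <- att$sample == s & att$gene == g
      for (k in sigs) {
        expected <- sum(att[rows, k])
        got <- cc$cca[cc$sample == s & cc$gene == g & cc$signature == k]
        expect_equal(got, expected, tolerance = 1e-12)
      }
    }
  }
})

test_that("adding a mutation in a gene only increases that gene's CCA", {
  fit <- toy_fit()
  r1 <- sbs_rec("s1", "C", "A", "A", "A", "TP53")
  r2 <- rbind(r1, sbs_rec("s1", "C", "T", "A", "T", "TP53"))
  cc1 <- compute_cca(attribute_mutations(r1, fit))
  cc2 <- compute_cca(attribute_mutations(r2, fit))
  tot1 <- sum(cc1$cca[cc1$gene == "TP53"])
  tot2 <- sum(cc2$cca[cc2$gene == "TP53"])
  expect_gt(tot2, tot1)
})

test_that("the feature matrix is gene-major, zero-filled and faithful", {
  att <- data.frame(sample = c("s1", "s2"), gene = c("A", "B"),
                    class = "A[C>A]A", s1 = c(0.7, 0.3), s2 = c(0.3, 0.7),
                    stringsAsFactors = FALSE)
  names(att)[4:5] <- c("sigA", "sigB")
  cc <- compute_cca(att)
  m <- cca_feature_matrix(cc, genes = c("A", "B", "ZZZ"),
                          signatures = c("sigA", "sigB"))
  expect_equal(colnames(m),
               c("A|sigA", "A|sigB", "B|sigA", "B|sigB",
                 "ZZZ|sigA", "ZZZ|sigB"))
  expect_equal(unname(m["s1", "A|sigA"]), 0.7)
  expect_equal(unname(m["s2", "B|sigB"]), 0.7)
  expect_equal(unname(m[, "ZZZ|sigA"]), c(0, 0))  # all-zero column kept

  # entry-by-entry equality with the long table on a simulated cohort
  sim <- simulate_cohort(sim_config(n_samples = 5, mean_mutations = 60,
                                    seed = 29))
  fit <- extract_signatures(build_catalog(sim$mutations), rank = 2,
                            n_restarts = 4, seed = 2)
  cc2 <- compute_cca(attribute_mutations(sim$mutations, fit))
  fm <- cca_feature_matrix(cc2)
  for (i in seq_len(nrow(cc2))) {
    expect_equal(fm[cc2$sample[i],
                    paste(cc2$gene[i], cc2$signature[i], sep = "|")],
                 cc2$cca[i], ignore_attr = TRUE)
  }
})

test_that("the normalized variant rescales each sample to unit mass", {
  sim <- simulate_cohort(sim_config(n_samples = 4, mean_mutations = 50,
                                    seed = 31))
  fit <- extract_signatures(build_catalog(sim$mutations), rank = 2,
                            n_restarts = 4, seed = 2)
  att <- attribute_mutations(sim$mutations, fit)
  ccn <- compute_cca(att, normalize = TRUE)
  tot <- tapply(ccn$cca, ccn$sample, sum)
  expect_equal(as.numeric(tot), rep(1, length(tot)), tolerance = 1e-9)
})
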