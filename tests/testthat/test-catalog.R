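test_that("substitutions classify into pyrimidine-collapsed context labels", {
  expect_equal(classify_substitution("C", "A", "A", "A"), "A[C>A]A")
  # purine ref: reverse-complement of 5'-TGC-3' is 5'-GCA-3', G>A -> C>T
  expect_equal(classify_substitution("G", "A", "T", "C"), "G[C>T]A")
  expect_equal(classify_substitution("A", "G", "C", "T"), "A[T>C]G")

  expect_error(classify_substitution("C", "C", "A", "A"), "ref == alt")
  expect_error(classify_substitution("N", "A", "A", "A"), "non-ACGT")
  expect_error(classify_substitution("C", "A", "N", "A"), "non-ACGT")
})

test_that("classification is exhaustive: 96 classes, 16 per type, 6 types", {
  bases <- c("A", "C", "G", "T")
  grid <- expand.grid(ref = bases, alt = bases, f5 = bases, f3 = bases,
                      stringsAsFactors = FALSE)
  grid <- grid[grid$ref != grid$alt, ]
  labs <- classify_substitution(grid$ref, grid$alt, grid$f5, grid$f3)
  expect_setequal(unique(labs), sbs_class_labels())
  expect_length(unique(labs), 96L)
  type <- sub("^.\\[(.>.)\\].$", "\\1", unique(labs))
  expect_equal(sort(unique(type)), sbs_substitution_types())
  expect_true(all(table(type) == 16L))
})

test_that("pyrimidine collapsing maps a purine input and its image together", {
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  bases <- c("A", "C", "G", "T")
  grid <- expand.grid(ref = c("A", "G"), alt = bases, f5 = bases, f3 = bases,
                      stringsAsFactors = FALSE)
  grid <- grid[grid$ref != grid$alt, ]
  direct <- classify_substitution(grid$ref, grid$alt, grid$f5, grid$f3)
  image <- classify_substitution(comp[grid$ref], comp[grid$alt],
                                 comp[grid$f3], comp[grid$f5])
  expect_equal(direct, image)
})

test_that("build_catalog tallies substitutions per sample", {
  recs <- rbind(sbs_rec("s1", "C", "T", "A", "T"),
                sbs_rec("s1", "G", "A", "T", "C"),
                sbs_rec("s1", "C", "T", "A", "T"))
  ct <- build_catalog(recs)
  expect_equal(unname(ct$counts["s1", "A[C>T]T"]), 2L)
  expect_equal(unname(ct$counts["s1", "G[C>T]A"]), 1L)
  expect_equal(sum(ct$counts), 3L)
})

test_that("indels count toward totals but not the 96-class matrix", {
  recs <- rbind(indel_rec(rep("s1", 4)), sbs_rec("s2", "C", "A", "A", "A"))
  ct <- build_catalog(recs)
  expect_equal(sum(ct$counts["s1", ]), 0L)
  expect_equal(unname(ct$totals["s1"]), 4L)
  expect_equal(unname(ct$totals["s2"]), 1L)
})

test_that("invalid SBS records are skipped with a warning and counted", {
  recs <- rbind(sbs_rec("s1", "C", "A", "A", "A"),
                sbs_rec("s1", "C", "A", "N", "A"),   # N flank
                sbs_rec("s1", "CA", "TG", "A", "A")) # MNV
  expect_warning(ct <- build_catalog(recs), "skipped 2")
  expect_equal(ct$n_skipped, 2L)
  expect_equal(sum(ct$counts), 1L)
})

test_that("catalog row sums match an independent per-sample SBS counter", {
  sim <- simulate_cohort(sim_config(n_samples = 12, mean_mutations = 80,
                                    seed = 301))
  ct <- build_catalog(sim$mutations)
  ref <- table(sim$mutations$sample[sim$mutations$variant_class == "SBS"])
  expect_equal(rowSums(ct$counts)[names(ref)], c(ref)[names(ref)],
               ignore_attr = TRUE)
  # totals include indels
  all_tot <- table(sim$mutations$sample)
  expect_equal(ct$totals[names(all_tot)], c(all_tot)[names(all_tot)],
               ignore_attr = TRUE)
})

test_that("hypermutation flagging is a strict monotone threshold rule", {
  fl <- flag_hypermutated(totals = c(s1 = 5, s2 = 5000), threshold = 1000)
  expect_equal(fl$is_hypermutated, c(FALSE, TRUE))
  fl2 <- flag_hypermutated(totals = c(s1 = 5, s2 = 5000), threshold = 6000)
  expect_false(any(fl2$is_hypermutated))
  # raising the threshold never enlarges the flagged set
  tot <- c(a = 10, b = 500, c = 1200, d = 9000)
  flagged <- lapply(c(100, 1000, 5000), function(th) {
    f <- flag_hypermutated(totals = tot, threshold = th)
    f$sample[f$is_hypermutated]
  })
  expect_true(all(flagged[[2]] %in% flagged[[1]]))
  expect_true(all(flagged[[3]] %in% flagged[[2]]))
})

test_that("a 7% hypermutator subpopulation is recovered at the threshold", {
  sim <- simulate_cohort(sim_config(n_samples = 300, mean_mutations = 100,
                                    hypermut_fraction = 0.07,
                                    hypermut_multiplier = 20, seed = 99))
  ct <- build_catalog(sim$mutations)
  fl <- flag_hypermutated(ct, threshold = 1000)
  frac <- mean(fl$is_hypermutated)
  expect_gt(frac, 0.03)
  expect_lt(frac, 0.12)
  expect_equal(fl$sample[fl$is_hypermutated],
               rownames(ct$counts)[sim$truth$hypermutated[
                 match(rownames(ct$counts), sprintf("SIM%03d", 1:300))]])
})

test_that("category proportions cover six classes and sum to one", {
  recs <- rbind(sbs_rec("s1", "C", "T", "A", "T"),
                sbs_rec("s1", "C", "T", "G", "G"))
  ct <- build_catalog(recs)
  p <- category_proportions(ct)
  expect_length(p, 6L)
  expect_equal(names(p), sbs_substitution_types())
  expect_equal(unname(p[["C>T"]]), 1.0)
  expect_equal(sum(p), 1, tolerance = 1e-9)

  # uniform catalog: each type gets exactly 1/6
  m <- matrix(1L, nrow = 2, ncol = 96,
              dimnames = list(c("a", "b"), sbs_class_labels()))
  expect_equal(unname(category_proportions(as_catalog(m))), rep(1 / 6, 6),
               tolerance = 1e-12)

  zero <- as_catalog(matrix(0L, 1, 96, dimnames = list("z", sbs_class_labels())))
  expect_error(category_proportions(zero), "all-zero")
})

test_that("MAF reading resolves flanks from bracket or sequence context", {
  maf <- data.frame(
    Tumor_Sample_Barcode = c("s1", "s1", "s2"),
    Chromosome = "chr5", Start_Position = c(100, 200, 300),
    Reference_Allele = c("C", "G", "A"),
    Tumor_Seq_Allele2 = c("T", "A", "AT"),
    Hugo_Symbol = c("TP53", "KRAS", "APC"),
    Variant_Type = c("SNP", "SNP", "INS"),
    ref_context = c("A[C>T]G", "TTGCA", NA),
    stringsAsFactors = FALSE)
  path <- withr::local_tempfile(fileext = ".maf")
  write.table(maf, path, sep = "\t", quote = FALSE, row.names = FALSE)
  recs <- read_maf(path)
  expect_equal(recs$flank5[1:2], c("A", "T"))
  expect_equal(recs$flank3[1:2], c("G", "C"))
  expect_equal(recs$variant_class, c("SBS", "SBS", "INDEL"))
  ct <- build_catalog(recs)
  expect_equal(unname(ct$counts["s1", "A[C>T]G"]), 1L)
  expect_equal(unname(ct$counts["s1", "G[C>T]A"]), 1L)  # collapsed T G>A A
})

test_that("catalog TSV round-trips in both layouts", {
  sim <- simulate_cohort(sim_config(n_samples = 5, mean_mutations = 50,
                                    seed = 7))
  ct <- build_catalog(sim$mutations)
  for (tr in c(FALSE, TRUE)) {
    path <- withr::local_tempfile(fileext = ".tsv")
    write_catalog(ct, path, transpose = tr)
    back <- read_catalog(path)
    expect_equal(back$counts, ct$counts)
  }
})
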