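test_that("trapezoidal AUC has the closed-form values", {
  r <- roc_with_ci(c(0.9, 0.8, 0.3, 0.1), c(TRUE, TRUE, FALSE, FALSE),
                   n_boot = 50)
  expect_equal(r$auc, 1.0)
  # one swap: 3 of 4 positive-negative pairs correctly ordered
  r2 <- roc_with_ci(c(0.9, 0.8, 0.3, 0.1), c(TRUE, FALSE, TRUE, FALSE),
                    n_boot = 50)
  expect_equal(r2$auc, 0.75)
  expect_error(roc_with_ci(c(1, 2), c(TRUE, TRUE), n_boot = 10),
               "both classes")
})

test_that("trapezoidal AUC equals the pair-counting statistic", {
  set.seed(61)
  for (rep in 1:20) {
    n <- sample(10:50, 1)
    scores <- sample(seq_len(1000), n)  # all distinct
    labels <- rbinom(n, 1, 0.5) == 1
    if (!any(labels) || all(labels)) next
    r <- roc_with_ci(scores, labels, n_boot = 10)
    expect_equal(r$auc, auc_pair_counting(scores, labels), tolerance = 1e-12)
  }
  # and with ties, via the 1/2 convention
  scores <- c(1, 1, 2, 2, 3)
  labels <- c(FALSE, TRUE, FALSE, TRUE, TRUE)
  r <- roc_with_ci(scores, labels, n_boot = 10)
  expect_equal(r$auc, auc_pair_counting(scores, labels), tolerance = 1e-12)
})

test_that("label-independent scores give a null AUC near one half", {
  set.seed(67)
  scores <- runif(1000)
  labels <- rbinom(1000, 1, 0.5) == 1
  r <- roc_with_ci(scores, labels, n_boot = 100)
  expect_gt(r$auc, 0.45)
  expect_lt(r$auc, 0.55)
})

test_that("the bootstrap CI brackets the point estimate inside [0, 1]", {
  set.seed(71)
  scores <- c(rnorm(40, 1), rnorm(40))
  labels <- rep(c(TRUE, FALSE), each = 40)
  r <- roc_with_ci(scores, labels, n_boot = 500, seed = 4)
  expect_lte(r$ci_low, r$auc)
  expect_gte(r$ci_high, r$auc)
  expect_gte(r$ci_low, 0)
  expect_lte(r$ci_high, 1)
  expect_true(all(diff(r$roc$tpr) >= 0))
  expect_true(all(diff(r$roc$fpr) >= 0))
})

test_that("the DeLong interval agrees closely with the bootstrap", {
  skip_if_not_installed("pROC")
  set.seed(73)
  scores <- c(rnorm(60, 0.8), rnorm(60))
  labels <- rep(c(TRUE, FALSE), each = 60)
  rb <- roc_with_ci(scores, labels, n_boot = 2000, seed = 1)
  rd <- roc_with_ci(scores, labels, ci_method = "delong")
  expect_equal(rb$auc, rd$auc)
  expect_lt(abs(rb$ci_low - rd$ci_low), 0.05)
  expect_lt(abs(rb$ci_high - rd$ci_high), 0.05)
})

# a feature matrix with a direct, clean signal for configuration tests
toy_learning_problem <- function(n = 120, p_decoy = 12, seed = 5) {
  set.seed(seed)
  y <- factor(rep(c("G1", "G2"), length.out = n))
  x <- matrix(rnorm(n * p_decoy), n, p_decoy,
              dimnames = list(paste0("c", 1:n),
                              paste0("DEC", seq_len(p_decoy), "|S")))
  signal <- ifelse(y == "G2", 3, 0) + rnorm(n, sd = 0.5)
  x <- cbind(x, "KEY|S" = signal)
  list(x = x, y = y)
}

test_that("the degenerate configuration collapses to one forest on all data", {
  tl <- toy_learning_problem()
  ctl <- fysr_control(subsample_fraction = 1, n_rounds = 1, freq_gate = 0,
                      importance_rule = "top_k", top_k = ncol(tl$x),
                      seed = 2)
  mod <- fysr(tl$x, tl$y, ctl, positive = "G2")
  expect_true(all(mod$selection$selected))
  expect_equal(mod$rounds_passed, 1L)
})

test_that("permuted labels leave no round able to pass the AUC gate", {
  tl <- toy_learning_problem(n = 200)
  set.seed(11)
  y_perm <- sample(tl$y)
  expect_error(fysr(tl$x, y_perm, fysr_control(n_rounds = 20, seed = 3)),
               "training-AUC gate")
})

test_that("raising freq_gate never grows the selected feature set", {
  tl <- toy_learning_problem()
  gates <- c(0.2, 0.5, 0.8)
  sels <- lapply(gates, function(fg) {
    mod <- fysr(tl$x, tl$y,
                fysr_control(n_rounds = 20, freq_gate = fg, seed = 7),
                positive = "G2")
    mod$selection$feature[mod$selection$selected]
  })
  expect_true(all(sels[[2]] %in% sels[[1]]))
  expect_true(all(sels[[3]] %in% sels[[2]]))
  expect_true("KEY|S" %in% sels[[3]])
})

test_that("training is reproducible given seed and config", {
  tl <- toy_learning_problem()
  m1 <- fysr(tl$x, tl$y, fysr_control(n_rounds = 10, seed = 13),
             positive = "G2")
  m2 <- fysr(tl$x, tl$y, fysr_control(n_rounds = 10, seed = 13),
             positive = "G2")
  expect_identical(m1$selection, m2$selection)
  expect_identical(m1$round_auc, m2$round_auc)
  expect_identical(predict(m1, tl$x), predict(m2, tl$x))
})

test_that("prediction is row-wise deterministic and tolerant of degenerate input", {
  tl <- toy_learning_problem()
  mod <- fysr(tl$x, tl$y, fysr_control(n_rounds = 10, seed = 17),
              positive = "G2")
  sc <- predict(mod, tl$x)
  expect_true(all(sc >= 0 & sc <= 1))
  # duplicated rows score identically
  dup <- tl$x[c(1, 1, 2), ]
  rownames(dup) <- c("a", "b", "c")
  sc_dup <- predict(mod, dup)
  expect_equal(unname(sc_dup["a"]), unname(sc_dup["b"]))
  # an all-zero row still gets a valid score
  zero <- matrix(0, 1, ncol(tl$x), dimnames = list("z", colnames(tl$x)))
  expect_true(predict(mod, zero) >= 0 && predict(mod, zero) <= 1)
  # missing model features are zero-filled with a warning
  expect_warning(predict(mod, tl$x[, 1:3, drop = FALSE]), "zero-filling")
})

test_that("single-class input is rejected", {
  tl <- toy_learning_problem()
  expect_error(fysr(tl$x, rep("G1", nrow(tl$x)), fysr_control(n_rounds = 2)),
               "two classes")
})

test_that("planted biomarkers are recovered through the full pipeline", {
  fs <- planted_feature_set(seed = 101)
  mod <- fysr(fs$x, fs$y, fysr_control(n_rounds = 30, seed = 9),
              positive = "G2")
  sel <- mod$selection$feature[mod$selection$selected]
  expect_true(all(fs$planted %in% sel))
  # at least 90% of decoys are rejected
  decoys <- setdiff(colnames(fs$x), fs$planted)
  expect_lte(sum(decoys %in% sel), 3L)
  # the refit model separates the training classes
  sc <- predict(mod, fs$x)
  r <- roc_with_ci(sc, fs$y == "G2", n_boot = 200, seed = 1)
  expect_gte(r$auc, 0.9)
})
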