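#' Extract mutational signatures by non-negative matrix factorization
#'
#' Factorises the catalog matrix V (96 classes x N samples) as V ~ W H with
#' W >= 0 (96 x K signature profiles) and H >= 0 (K x N exposures). The
#' objective is the generalized Kullback-Leibler divergence, the natural
#' choice for Poisson-like mutation counts, minimised by multiplicative
#' updates from strictly positive random initialisations; the best of
#' \code{n_restarts} runs (lowest objective, ties broken by restart index)
#' is kept. A squared-error (Frobenius) objective is available via
#' \code{objective = "frobenius"}.
#'
#' After the winning restart, W is column-normalized (each profile sums to 1)
#' with the scale absorbed into H, and H is then refit per sample against the
#' fixed W on the same objective, so that each sample's activities sum close
#' to its mutation count ("attributed mutations"). Signatures are ordered by
#' descending total activity and given provisional names S1..SK.
#'
#' @param catalog a \code{mut_catalog} (see [build_catalog()]).
#' @param rank number of signatures K, with 1 <= K < min(96, n samples).
#' @param n_restarts random restarts (default 20).
#' @param max_iter maximum multiplicative-update iterations per restart.
#' @param seed integer seed; the run is fully deterministic given it.
#' @param tol convergence tolerance: stop when the relative objective change
#'   over 10 iterations falls below \code{tol}.
#' @param objective \code{"kl"} (default) or \code{"frobenius"}.
#' @return An object of class \code{sig_nmf}: list with \code{signatures}
#'   (96 x K column-stochastic matrix), \code{exposures} (K x N attributed
#'   counts), \code{relative} (K x N per-sample fractions; all-zero columns
#'   for zero-mutation samples, flagged in \code{zero_samples}), \code{rank},
#'   \code{reconstruction_error}, \code{restarts_used}, \code{seed},
#'   \code{objective}.
#' @export
extract_signatures <- function(catalog, rank, n_restarts = 20,
                               max_iter = 2000, seed = 1, tol = 1e-6,
                               objective = c("kl", "frobenius")) {
  stopifnot(inherits(catalog, "mut_catalog"))
  objective <- match.arg(objective)
  V <- t(catalog$counts)  # 96 x N
  if (sum(V) == 0) stop("all-zero catalog cannot be factorized")
  if (rank < 1 || rank >= min(nrow(V), ncol(V))) {
    stop("rank must satisfy 1 <= K < min(96, n_samples)")
  }
  runs <- .nmf_restarts(V, rank, n_restarts, max_iter, seed, tol, objective)
  best <- runs[[which.min(vapply(runs, `[[`, numeric(1), "error"))]]

  W <- best$W
  H <- best$H
  scale <- colSums(W)
  W <- sweep(W, 2, scale, "/")
  H <- H * scale
  # per-sample exposure refit against the fixed, normalized profiles
  H <- refit_exposures(W, V, H0 = H, max_iter = max_iter, tol = tol,
                       objective = objective)
  ord <- order(rowSums(H), decreasing = TRUE)
  W <- W[, ord, drop = FALSE]
  H <- H[ord, , drop = FALSE]
  ids <- paste0("S", seq_len(rank))
  colnames(W) <- ids
  rownames(H) <- ids
  rownames(W) <- rownames(V)
  colnames(H) <- colnames(V)

  rel <- relative_exposures(H)
  structure(list(signatures = W, exposures = H,
                 relative = rel$relative, zero_samples = rel$zero_samples,
                 rank = rank,
                 reconstruction_error = .nmf_objective(V, W %*% H, objective),
                 restarts_used = n_restarts, seed = seed,
                 objective = objective,
                 restart_errors = vapply(runs, `[[`, numeric(1), "error")),
            class = "sig_nmf")
}

.nmf_restarts <- function(V, rank, n_restarts, max_iter, seed, tol,
                          objective) {
  old <- if (exists(".Random.seed", .GlobalEnv)) {
    get(".Random.seed", .GlobalEnv)
  }
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(seed)
  lapply(seq_len(n_restarts), function(i) {
    W0 <- matrix(stats::runif(nrow(V) * rank, 0.1, 1), nrow(V), rank)
    H0 <- matrix(stats::runif(rank * ncol(V), 0.1, 1) * mean(V) * 2,
                 rank, ncol(V))
    .nmf_fit(V, W0, H0, max_iter, tol, objective)
  })
}

.nmf_objective <- function(V, WH, objective) {
  if (objective == "kl") {
    pos <- V > 0
    sum(V[pos] * log(V[pos] / WH[pos])) - sum(V) + sum(WH)
  } else {
    sum((V - WH)^2) / 2
  }
}

.nmf_fit <- function(V, W, H, max_iter, tol, objective, update_w = TRUE) {
  eps <- .Machine$double.eps
  err_prev <- Inf
  err <- .nmf_objective(V, W %*% H, objective)
  trace <- numeric(0)
  for (it in seq_len(max_iter)) {
    if (objective == "kl") {
      WH <- W %*% H
      H <- H * (t(W) %*% (V / pmax(WH, eps))) / pmax(colSums(W), eps)
      if (update_w) {
        WH <- W %*% H
        W <- W * ((V / pmax(WH, eps)) %*% t(H)) /
          pmax(matrix(rowSums(H), nrow(W), ncol(W), byrow = TRUE), eps)
      }
    } else {
      H <- H * (t(W) %*% V) / pmax(t(W) %*% W %*% H, eps)
      if (update_w) {
        W <- W * (V %*% t(H)) / pmax(W %*% H %*% t(H), eps)
      }
    }
    if (it %% 10L == 0L) {
      err_prev <- err
      err <- .nmf_objective(V, W %*% H, objective)
      trace <- c(trace, err)
      if (is.finite(err_prev) &&
          abs(err_prev - err) <= tol * max(abs(err_prev), eps)) break
    }
  }
  list(W = W, H = H, error = .nmf_objective(V, W %*% H, objective),
       iterations = it, trace = trace)
}

#' Refit exposures for fixed signature profiles
#'
#' Holds the column-stochastic profile matrix W fixed and updates only the
#' per-sample activities H under the chosen objective (non-negative
#' regression per sample). With the KL objective and column-stochastic W,
#' converged activities for each sample sum to that sample's mutation count.
#'
#' @param W 96 x K column-stochastic profile matrix.
#' @param V 96 x N count matrix (a transposed catalog), or a
#'   \code{mut_catalog}.
#' @param H0 optional K x N starting activities.
#' @param max_iter,tol as in [extract_signatures()].
#' @param objective \code{"kl"} or \code{"frobenius"}.
#' @return K x N non-negative activity matrix.
#' @export
refit_exposures <- function(W, V, H0 = NULL, max_iter = 2000, tol = 1e-6,
                            objective = "kl") {
  if (inherits(V, "mut_catalog")) V <- t(V$counts)
  stopifnot(nrow(W) == nrow(V))
  K <- ncol(W)
  if (is.null(H0)) {
    H0 <- matrix(colSums(V) / K, K, ncol(V), byrow = TRUE) + 1e-3
  }
  fit <- .nmf_fit(V, W, pmax(H0, 1e-9), max_iter, tol, objective,
                  update_w = FALSE)
  H <- fit$H
  dimnames(H) <- list(colnames(W), colnames(V))
  H
}

#' Per-sample relative signature exposures
#'
#' @param exposures K x N activity matrix (or a \code{sig_nmf} object).
#' @return list with \code{relative} (column-stochastic K x N matrix;
#'   all-zero columns left at zero) and \code{zero_samples} (names of
#'   samples with zero total activity).
#' @export
relative_exposures <- function(exposures) {
  if (inherits(exposures, "sig_nmf")) exposures <- exposures$exposures
  tot <- colSums(exposures)
  rel <- sweep(exposures, 2, ifelse(tot > 0, tot, 1), "/")
  rel[, tot == 0] <- 0
  list(relative = rel,
       zero_samples = colnames(exposures)[tot == 0])
}

#' @export
print.sig_nmf <- function(x, ...) {
  cat(sprintf(
    "NMF signature model: K = %d, %d samples, %s objective\n",
    x$rank, ncol(x$exposures), toupper(x$objective)))
  cat(sprintf("reconstruction error: %.4g (best of %d restarts, seed %d)\n",
              x$reconstruction_error, x$restarts_used, x$seed))
  cat("total attributed mutations per signature:\n")
  print(round(rowSums(x$exposures), 1))
  invisible(x)
}

#' @export
summary.sig_nmf <- function(object, ...) {
  print(object)
  cat("\nper-sample relative exposure quartiles:\n")
  print(t(apply(object$relative, 1, stats::quantile,
                probs = c(0.25, 0.5, 0.75))))
  invisible(object)
}

#' Barplot of extracted signature profiles
#'
#' @param x a \code{sig_nmf}.
#' @param signatures which signatures to draw (default all).
#' @param ... passed to [graphics::barplot()].
#' @export
plot.sig_nmf <- function(x, signatures = colnames(x$signatures), ...) {
  cols <- rep(c("#03BCEE", "#010101", "#E32926",
                "#CAC9C9", "#A1CE63", "#EBC6C4"), each = 16L)
  old <- graphics::par(mfrow = c(length(signatures), 1),
                       mar = c(1, 4, 2, 1))
  on.exit(graphics::par(old))
  for (s in signatures) {
    graphics::barplot(x$signatures[, s], col = cols, border = NA,
                      names.arg = FALSE, main = s, ylab = "probability", ...)
  }
  invisible(x)
}

#' Choose the number of signatures by error and restart stability
#'
#' Runs the factorization over a grid of ranks and reports, per K, the
#' best-restart reconstruction error and a stability score: the mean cosine
#' similarity between each restart's profiles and the best restart's
#' profiles after greedy one-to-one matching. The chosen K is the smallest
#' K below \code{k_max} whose stability is at least \code{stability_floor}
#' and whose relative error improvement moving to K+1 falls below
#' \code{improvement_ratio} (the elbow); if no K qualifies, the K with the
#' highest stability is returned.
#'
#' @param catalog a \code{mut_catalog}.
#' @param k_min,k_max rank grid bounds.
#' @param n_restarts,max_iter,seed,tol,objective as in
#'   [extract_signatures()].
#' @param stability_floor minimum acceptable mean matched cosine.
#' @param improvement_ratio relative error-improvement cutoff.
#' @return list with \code{rank} (chosen K) and \code{diagnostics}
#'   (data.frame of K, reconstruction_error, stability).
#' @export
select_rank <- function(catalog, k_min, k_max, n_restarts = 20,
                        max_iter = 2000, seed = 1, tol = 1e-6,
                        objective = "kl",
                        stability_floor = 0.9, improvement_ratio = 0.1) {
  stopifnot(1 <= k_min, k_min <= k_max)
  V <- t(catalog$counts)
  if (k_max >= min(nrow(V), ncol(V))) {
    stop("k_max must be below min(96, n_samples)")
  }
  ks <- k_min:k_max
  errs <- numeric(length(ks))
  stab <- numeric(length(ks))
  for (i in seq_along(ks)) {
    runs <- .nmf_restarts(V, ks[i], n_restarts, max_iter, seed + i, tol,
                          objective)
    es <- vapply(runs, `[[`, numeric(1), "error")
    best <- runs[[which.min(es)]]
    errs[i] <- min(es)
    Wb <- sweep(best$W, 2, pmax(colSums(best$W), 1e-12), "/")
    sims <- vapply(runs, function(r) {
      Wr <- sweep(r$W, 2, pmax(colSums(r$W), 1e-12), "/")
      mean(.match_profiles(Wb, Wr))
    }, numeric(1))
    stab[i] <- mean(sims)
  }
  diag <- data.frame(K = ks, reconstruction_error = errs, stability = stab)
  chosen <- NA_integer_
  if (length(ks) == 1L) {
    chosen <- ks
  } else {
    for (i in seq_len(length(ks) - 1L)) {
      improv <- (errs[i] - errs[i + 1]) / max(errs[i], .Machine$double.eps)
      if (stab[i] >= stability_floor && improv < improvement_ratio) {
        chosen <- ks[i]
        break
      }
    }
    if (is.na(chosen)) chosen <- ks[which.max(stab)]
  }
  list(rank = chosen, diagnostics = diag)
}

# greedy one-to-one matching of columns of B to columns of A by cosine;
# returns the matched cosines (length ncol(A))
.match_profiles <- function(A, B) {
  K <- ncol(A)
  sim <- matrix(0, K, K)
  for (i in seq_len(K)) {
    for (j in seq_len(K)) sim[i, j] <- cosine_similarity(A[, i], B[, j])
  }
  out <- numeric(K)
  for (step in seq_len(K)) {
    idx <- arrayInd(which.max(sim), dim(sim))
    out[idx[1]] <- sim[idx[1], idx[2]]
    sim[idx[1], ] <- -Inf
    sim[, idx[2]] <- -Inf
  }
  out
}

#' Write signature / exposure tables
#'
#' @param fit a \code{sig_nmf}.
#' @param prefix output path prefix; writes
#'   \code{<prefix>.signatures.tsv} (96 rows x K, COSMIC layout),
#'   \code{<prefix>.exposures.tsv} (K x N attributed counts) and
#'   \code{<prefix>.exposures.relative.tsv}.
#' @export
write_signature_fit <- function(fit, prefix) {
  stopifnot(inherits(fit, "sig_nmf"))
  sig <- data.frame(Type = rownames(fit$signatures), fit$signatures,
                    check.names = FALSE)
  utils::write.table(sig, paste0(prefix, ".signatures.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  for (piece in c("exposures", "relative")) {
    m <- fit[[piece]]
    df <- data.frame(Signature = rownames(m), m, check.names = FALSE)
    suffix <- if (piece == "relative") ".exposures.relative.tsv"
              else ".exposures.tsv"
    utils::write.table(df, paste0(prefix, suffix), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  invisible(prefix)
}
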