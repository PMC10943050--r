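#' Training configuration for the five-year-survival model
#'
#' @param subsample_fraction fraction of cases drawn (without replacement,
#'   class-stratified) in each selection round; default 0.95.
#' @param n_rounds number of subsampling rounds.
#' @param auc_gate rounds whose out-of-bag training AUC does not exceed this
#'   gate contribute nothing to feature selection; default 0.9.
#' @param freq_gate a feature is selected when its selection frequency over
#'   the gate-passing rounds strictly exceeds this gate; default 0.5.
#' @param num_trees forest size per round; default 500.
#' @param mtry features per split; default the square root of the feature
#'   count (the forest default, applied at fit time when NULL).
#' @param importance_rule per-round feature criterion: \code{"above_mean"}
#'   (impurity importance above the round's mean importance, the default) or
#'   \code{"top_k"}.
#' @param top_k number of features kept per round when
#'   \code{importance_rule = "top_k"}.
#' @param seed integer seed making the whole procedure reproducible.
#' @return list of class \code{fysr_control}.
#' @export
fysr_control <- function(subsample_fraction = 0.95, n_rounds = 100,
                         auc_gate = 0.9, freq_gate = 0.5,
                         num_trees = 500, mtry = NULL,
                         importance_rule = c("above_mean", "top_k"),
                         top_k = 10, seed = 1) {
  stopifnot(subsample_fraction > 0, subsample_fraction <= 1,
            freq_gate >= 0, freq_gate <= 1, n_rounds >= 1)
  structure(list(subsample_fraction = subsample_fraction,
                 n_rounds = n_rounds, auc_gate = auc_gate,
                 freq_gate = freq_gate, num_trees = num_trees, mtry = mtry,
                 importance_rule = match.arg(importance_rule),
                 top_k = top_k, seed = as.integer(seed)),
            class = "fysr_control")
}

#' Train the five-year-survival random-forest model
#'
#' Implements the repeated-subsampling biomarker selection procedure: in
#' each round a class-stratified 95 percent subsample of cases is drawn
#' without replacement and a probability random forest is fit on it. Rounds
#' whose training AUC (computed from out-of-bag predictions on the
#' subsample) exceeds the AUC gate contribute their top-importance features
#' — by default those with impurity importance above the round's mean — to
#' the selection tally. Features selected in more than \code{freq_gate} of
#' the gate-passing rounds (the screened models) become the biomarker
#' panel, and the final forest is refit on
#' all cases restricted to that panel.
#'
#' @param x samples x features numeric matrix (e.g. from
#'   [cca_feature_matrix()]), feature names \code{"GENE|SIG"}.
#' @param y binary outcome: factor or vector with exactly two levels; the
#'   second level after factoring (e.g. "G2" against "G1") is scored as the
#'   positive class unless \code{positive} says otherwise.
#' @param control a [fysr_control()].
#' @param positive which level of \code{y} the predicted score is the
#'   probability of (default: the first level alphabetically falling last —
#'   set explicitly when it matters).
#' @return An object of class \code{fysr}: \code{selection} (data.frame of
#'   feature, selection count, frequency, selected flag), \code{ensemble}
#'   (the final ranger forest), \code{rounds_passed}, \code{round_auc},
#'   \code{control}, \code{positive}, \code{levels}.
#' @export
fysr <- function(x, y, control = fysr_control(), positive = NULL) {
  stopifnot(inherits(control, "fysr_control"))
  x <- as.matrix(x)
  if (is.null(colnames(x))) {
    colnames(x) <- paste0("f", seq_len(ncol(x)))
  }
  y <- factor(y)
  if (nlevels(y) != 2) stop("outcome must have exactly two classes")
  if (is.null(positive)) positive <- levels(y)[2]
  stopifnot(positive %in% levels(y))

  ctl <- control
  counts <- stats::setNames(numeric(ncol(x)), colnames(x))
  round_auc <- rep(NA_real_, ctl$n_rounds)
  passed <- 0L
  idx_by_class <- split(seq_along(y), y)

  for (r in seq_len(ctl$n_rounds)) {
    rs <- ctl$seed + r
    set.seed(rs)
    take <- unlist(lapply(idx_by_class, function(ii) {
      n_take <- max(1L, round(length(ii) * ctl$subsample_fraction))
      sample(ii, n_take)
    }), use.names = FALSE)
    xt <- x[take, , drop = FALSE]
    yt <- droplevels(y[take])
    if (nlevels(yt) != 2) next
    rf <- .fit_forest(xt, yt, ctl, seed = rs)
    oob <- rf$predictions[, positive]
    usable <- !is.na(oob)
    if (length(unique(yt[usable])) != 2) next
    round_auc[r] <- .auc_trapezoid(oob[usable],
                                   yt[usable] == positive)
    if (round_auc[r] > ctl$auc_gate) {
      passed <- passed + 1L
      imp <- rf$variable.importance
      top <- if (ctl$importance_rule == "above_mean") {
        names(imp)[imp > mean(imp)]
      } else {
        names(sort(imp, decreasing = TRUE))[seq_len(min(ctl$top_k,
                                                        length(imp)))]
      }
      counts[top] <- counts[top] + 1
    }
  }
  if (passed == 0L) {
    stop("no subsampling round passed the training-AUC gate (",
         ctl$auc_gate, "); relax auc_gate or check the features")
  }
  freq <- counts / passed
  selected <- freq > ctl$freq_gate
  if (!any(selected)) {
    stop("no feature exceeded the selection-frequency gate (",
         ctl$freq_gate, "); relax freq_gate")
  }
  selection <- data.frame(feature = names(counts),
                          selection_count = as.integer(counts),
                          frequency = freq, selected = selected,
                          row.names = NULL, stringsAsFactors = FALSE)
  selection <- selection[order(-selection$frequency, selection$feature), ]
  rownames(selection) <- NULL

  final <- .fit_forest(x[, selected, drop = FALSE], y, ctl,
                       seed = ctl$seed)
  structure(list(selection = selection, ensemble = final,
                 rounds_passed = passed, round_auc = round_auc,
                 control = ctl, positive = positive, levels = levels(y)),
            class = "fysr")
}

.fit_forest <- function(x, y, ctl, seed) {
  mtry <- ctl$mtry
  if (is.null(mtry)) mtry <- max(1L, floor(sqrt(ncol(x))))
  mtry <- min(mtry, ncol(x))
  ranger::ranger(x = x, y = y, probability = TRUE,
                 num.trees = ctl$num_trees, mtry = mtry,
                 importance = "impurity", seed = seed,
                 num.threads = 1)
}

#' @export
print.fysr <- function(x, ...) {
  sel <- x$selection[x$selection$selected, , drop = FALSE]
  genes <- unique(sub("\\|.*$", "", sel$feature))
  cat(sprintf(
    "five-year-survival forest: %d biomarker feature(s) over %d gene(s)\n",
    nrow(sel), length(genes)))
  cat(sprintf(
    "%d of %d subsampling rounds passed the AUC gate (> %.2f)\n",
    x$rounds_passed, x$control$n_rounds, x$control$auc_gate))
  cat(sprintf("positive class: %s\n", x$positive))
  print(utils::head(sel, 20), row.names = FALSE)
  invisible(x)
}

#' @export
summary.fysr <- function(object, ...) {
  print(object)
  cat("\nround training AUC (gate-passing rounds):\n")
  print(summary(object$round_auc[!is.na(object$round_auc)]))
  invisible(object)
}

#' Predict five-year-survival scores
#'
#' @param object a fitted \code{fysr} model.
#' @param newdata samples x features matrix; features the model selected but
#'   the matrix lacks are zero-filled with a warning, extra columns are
#'   ignored.
#' @param ... unused.
#' @return numeric vector of per-sample probabilities of the model's
#'   positive class, in [0, 1].
#' @export
predict.fysr <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  feats <- object$ensemble$forest$independent.variable.names
  missing <- setdiff(feats, colnames(newdata))
  if (length(missing)) {
    warning("zero-filling ", length(missing),
            " feature(s) absent from newdata")
    pad <- matrix(0, nrow(newdata), length(missing),
                  dimnames = list(rownames(newdata), missing))
    newdata <- cbind(newdata, pad)
  }
  pr <- stats::predict(object$ensemble,
                       data = newdata[, feats, drop = FALSE],
                       num.threads = 1)$predictions
  stats::setNames(pr[, object$positive], rownames(newdata))
}

# trapezoidal AUC over the empirical ROC (equivalently the tie-corrected
# Mann-Whitney statistic)
.auc_trapezoid <- function(scores, is_pos) {
  roc <- .roc_points(scores, is_pos)
  sum(diff(roc$fpr) * (utils::head(roc$tpr, -1) + utils::tail(roc$tpr, -1)) / 2)
}

.roc_points <- function(scores, is_pos) {
  np <- sum(is_pos)
  nn <- sum(!is_pos)
  stopifnot(np > 0, nn > 0)
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]
  p <- is_pos[ord]
  # collapse score ties into single ROC steps
  tp <- cumsum(p)
  fp <- cumsum(!p)
  last <- c(s[-1] != s[-length(s)], TRUE)
  data.frame(fpr = c(0, fp[last] / nn), tpr = c(0, tp[last] / np))
}

#' ROC curve, AUC and 95 percent confidence interval
#'
#' AUC is the area under the empirical ROC by the trapezoidal rule. The
#' confidence interval comes from a stratified bootstrap (resampling
#' positives and negatives separately, default 2000 replicates, percentile
#' interval) or, with \code{ci_method = "delong"}, from the DeLong
#' asymptotic variance (via the pROC package). Bounds are clipped to
#' [0, 1].
#'
#' @param scores numeric predicted scores.
#' @param labels binary labels (logical, or a two-level factor/vector whose
#'   second level is positive).
#' @param ci_method \code{"bootstrap"} (default) or \code{"delong"}.
#' @param n_boot bootstrap replicates.
#' @param seed seed for the bootstrap.
#' @param conf confidence level, default 0.95.
#' @return An object of class \code{roc_summary}: \code{auc},
#'   \code{ci_low}, \code{ci_high}, \code{roc} (data.frame of fpr, tpr),
#'   \code{n_pos}, \code{n_neg}, \code{ci_method}.
#' @export
roc_with_ci <- function(scores, labels, ci_method = c("bootstrap", "delong"),
                        n_boot = 2000, seed = 1, conf = 0.95) {
  ci_method <- match.arg(ci_method)
  if (is.logical(labels)) {
    is_pos <- labels
  } else {
    f <- factor(labels)
    if (nlevels(f) != 2) stop("labels must have exactly two classes")
    is_pos <- f == levels(f)[2]
  }
  if (!any(is_pos) || all(is_pos)) stop("both classes must be present")
  roc <- .roc_points(scores, is_pos)
  auc <- .auc_trapezoid(scores, is_pos)
  alpha <- (1 - conf) / 2
  if (ci_method == "bootstrap") {
    old <- if (exists(".Random.seed", .GlobalEnv)) {
      get(".Random.seed", .GlobalEnv)
    }
    on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
    set.seed(seed)
    ip <- which(is_pos)
    ineg <- which(!is_pos)
    boots <- vapply(seq_len(n_boot), function(b) {
      bi <- c(sample(ip, length(ip), replace = TRUE),
              sample(ineg, length(ineg), replace = TRUE))
      .auc_trapezoid(scores[bi], is_pos[bi])
    }, numeric(1))
    ci <- stats::quantile(boots, c(alpha, 1 - alpha), names = FALSE)
  } else {
    if (!requireNamespace("pROC", quietly = TRUE)) {
      stop("ci_method = 'delong' requires the pROC package")
    }
    r <- pROC::roc(response = is_pos, predictor = scores,
                   levels = c(FALSE, TRUE), direction = "<", quiet = TRUE)
    ci <- as.numeric(pROC::ci.auc(r, method = "delong",
                                  conf.level = conf))[c(1, 3)]
  }
  ci <- pmin(pmax(ci, 0), 1)
  structure(list(auc = auc, ci_low = ci[1], ci_high = ci[2], roc = roc,
                 n_pos = sum(is_pos), n_neg = sum(!is_pos),
                 ci_method = ci_method, conf = conf),
            class = "roc_summary")
}

#' @export
print.roc_summary <- function(x, ...) {
  cat(sprintf("AUC: %.4f, %d%% CI: %.4f-%.4f (%s; %d pos / %d neg)\n",
              x$auc, round(100 * x$conf), x$ci_low, x$ci_high,
              x$ci_method, x$n_pos, x$n_neg))
  invisible(x)
}

#' @export
plot.roc_summary <- function(x, ...) {
  graphics::plot(x$roc$fpr, x$roc$tpr, type = "l", lwd = 2,
                 xlab = "false positive rate", ylab = "true positive rate",
                 ...)
  graphics::abline(0, 1, lty = 3, col = "grey")
  graphics::mtext(sprintf("AUC %.3f (%.3f-%.3f)", x$auc, x$ci_low,
                          x$ci_high), side = 3)
  invisible(x)
}

#' Write the biomarker selection table and ROC summary
#'
#' @param model a \code{fysr} fit.
#' @param roc optional \code{roc_summary} to write alongside.
#' @param prefix output prefix; writes \code{<prefix>.selection.tsv} and,
#'   when given, \code{<prefix>.roc.tsv}.
#' @export
write_fysr <- function(model, prefix, roc = NULL) {
  utils::write.table(model$selection, paste0(prefix, ".selection.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(roc)) {
    utils::write.table(roc$roc, paste0(prefix, ".roc.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  invisible(prefix)
}
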