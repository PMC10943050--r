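#' Read a clinical follow-up table
#'
#' @param path TSV with columns \code{sample_id}, \code{survival_months},
#'   \code{vital_status} (dead / alive / unknown; case-insensitive).
#' @return data.frame with \code{sample}, \code{survival_months} (numeric,
#'   NA when missing) and \code{event} (factor dead/alive/unknown).
#' @export
read_clinical <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  needed <- c("sample_id", "survival_months", "vital_status")
  missing <- setdiff(needed, names(df))
  if (length(missing)) {
    stop("clinical table lacks column(s): ", paste(missing, collapse = ", "))
  }
  clinical_records(data.frame(sample = df$sample_id,
                              survival_months = df$survival_months,
                              event = df$vital_status,
                              stringsAsFactors = FALSE))
}

#' Validate a clinical record table
#'
#' @param df data.frame with \code{sample}, \code{survival_months},
#'   \code{event}.
#' @return the normalised data.frame.
#' @export
clinical_records <- function(df) {
  needed <- c("sample", "survival_months", "event")
  missing <- setdiff(needed, names(df))
  if (length(missing)) {
    stop("clinical table lacks column(s): ", paste(missing, collapse = ", "))
  }
  df$sample <- as.character(df$sample)
  df$survival_months <- suppressWarnings(as.numeric(df$survival_months))
  ev <- tolower(as.character(df$event))
  ev[is.na(ev) | !(ev %in% c("dead", "alive"))] <- "unknown"
  df$event <- ev
  if (any(df$survival_months < 0, na.rm = TRUE)) {
    stop("negative survival times")
  }
  df[, needed]
}

#' Assign samples to the four five-year-survival cohort groups
#'
#' G1: survival longer than 60 months (regardless of vital status).
#' G2: survival under five years ending in death. G3: survival under five
#' years, alive at last follow-up (right-censored). G4: survival time or
#' vital status missing. Exactly 60 months falls in G2/G3 by status, since
#' G1 requires strictly more than five years.
#'
#' @param clinical a clinical record table (see [clinical_records()]).
#' @return data.frame with \code{sample} and \code{group} (factor G1-G4);
#'   every sample lands in exactly one group.
#' @export
assign_groups <- function(clinical) {
  clinical <- clinical_records(clinical)
  if (anyDuplicated(clinical$sample)) {
    stop("duplicate sample ids in clinical table")
  }
  t <- clinical$survival_months
  ev <- clinical$event
  group <- ifelse(is.na(t) | ev == "unknown", "G4",
           ifelse(t > 60, "G1",
           ifelse(ev == "dead", "G2", "G3")))
  data.frame(sample = clinical$sample,
             group = factor(group, levels = c("G1", "G2", "G3", "G4")),
             stringsAsFactors = FALSE)
}

#' Kaplan-Meier stratification by signature exposure threshold
#'
#' Splits samples into a high-exposure arm (relative exposure strictly above
#' the threshold) and a low arm, fits a Kaplan-Meier estimate per arm, and
#' compares the arms with a two-sided log-rank test. Samples without usable
#' clinical information (group G4) are excluded; alive samples are
#' right-censored at their recorded follow-up time.
#'
#' @param exposure named per-sample relative exposure for one signature
#'   (fractions in [0, 1]).
#' @param clinical clinical record table (see [clinical_records()]).
#' @param threshold exposure cut in (0, 1); default 0.2, i.e. "more than
#'   20 percent of the sample's mutations attributed to the signature".
#' @param absolute if TRUE, \code{exposure} is interpreted as absolute
#'   attributed counts and \code{threshold} on that scale.
#' @return An object of class \code{km_strat}: threshold, per-arm sizes,
#'   log-rank statistic and p-value, per-arm median survival (NA when not
#'   reached), the underlying \code{survfit}, and \code{test_defined}
#'   (FALSE when an arm has fewer than 2 samples, in which case no test is
#'   run).
#' @export
stratify_by_exposure <- function(exposure, clinical, threshold = 0.2,
                                 absolute = FALSE) {
  if (!absolute && (threshold <= 0 || threshold >= 1)) {
    stop("threshold must lie in (0, 1)")
  }
  clinical <- clinical_records(clinical)
  groups <- assign_groups(clinical)
  keep <- groups$group != "G4" & clinical$sample %in% names(exposure)
  cl <- clinical[keep, , drop = FALSE]
  expo <- exposure[cl$sample]
  arm <- factor(ifelse(expo > threshold, "high", "low"),
                levels = c("low", "high"))
  time <- cl$survival_months
  status <- as.integer(cl$event == "dead")

  n_high <- sum(arm == "high")
  n_low <- sum(arm == "low")
  test_defined <- n_high >= 2 && n_low >= 2

  fit <- NULL
  medians <- c(low = NA_real_, high = NA_real_)
  stat <- NA_real_
  p <- NA_real_
  if (test_defined) {
    fit <- survival::survfit(survival::Surv(time, status) ~ arm)
    sm <- summary(fit)$table
    medians <- stats::setNames(sm[, "median"], sub("^arm=", "", rownames(sm)))
    sd <- survival::survdiff(survival::Surv(time, status) ~ arm)
    stat <- sd$chisq
    p <- stats::pchisq(sd$chisq, df = 1, lower.tail = FALSE)
  } else if (n_high + n_low >= 2) {
    fit <- survival::survfit(survival::Surv(time, status) ~ 1)
  }
  structure(list(threshold = threshold, absolute = absolute,
                 n_high = n_high, n_low = n_low,
                 logrank_statistic = stat, p_value = p,
                 median_survival = medians,
                 survfit = fit, test_defined = test_defined),
            class = "km_strat")
}

#' @export
print.km_strat <- function(x, ...) {
  cat(sprintf("exposure stratification at %s %s\n",
              if (x$absolute) "count >" else "fraction >",
              format(x$threshold)))
  cat(sprintf("arms: high n=%d, low n=%d\n", x$n_high, x$n_low))
  if (x$test_defined) {
    cat(sprintf("log-rank chi-square = %.3f, p = %.4g\n",
                x$logrank_statistic, x$p_value))
    cat("median survival (months): low =",
        format(x$median_survival[["low"]]),
        ", high =", format(x$median_survival[["high"]]), "\n")
  } else {
    cat("log-rank test undefined: an arm has fewer than 2 samples\n")
  }
  invisible(x)
}

#' Kaplan-Meier curves for an exposure stratification
#'
#' @param x a \code{km_strat}.
#' @param ... passed to \code{plot.survfit}.
#' @export
plot.km_strat <- function(x, ...) {
  if (is.null(x$survfit)) stop("no survival fit available to plot")
  graphics::plot(x$survfit, col = c("#1f77b4", "#d62728"),
                 xlab = "months", ylab = "survival probability", ...)
  if (x$test_defined) {
    graphics::legend("topright", bty = "n",
                     col = c("#1f77b4", "#d62728"), lty = 1,
                     legend = c(sprintf("low (n=%d)", x$n_low),
                                sprintf("high (n=%d)", x$n_high)))
    graphics::mtext(sprintf("log-rank p = %.3g", x$p_value), side = 3)
  }
  invisible(x)
}
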