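#' Deterministic synthetic reference signature panel
#'
#' Builds a small, fully deterministic panel of eight synthetic 96-class
#' profiles carrying COSMIC-style names (SBS1, SBS2, SBS3, SBS17a, SBS17b,
#' SBS18, SBS44, SBS52). The shapes are loosely evocative of the processes
#' those names usually denote (CpG C>T spikes for "SBS1", a C[T>G]T spike
#' for "SBS17b", broad C>A for "SBS18", a C>T plus T>C mix for "SBS44", ...)
#' but they are synthetic stand-ins, not the published reference profiles.
#' All pairwise cosine similarities are below 0.5, so matching against the
#' panel is unambiguous in tests and examples.
#'
#' @return A \code{ref_panel} (see [ref_panel()]).
#' @export
make_fixture_panel <- function() {
  labels <- sbs_class_labels()
  block <- function(type_idx) ((type_idx - 1L) * 16L + 1L):(type_idx * 16L)
  bidx <- c(A = 1L, C = 2L, G = 3L, T = 4L)
  ctx <- function(type_idx, f5, f3) {
    (type_idx - 1L) * 16L + 4L * (bidx[[f5]] - 1L) + bidx[[f3]]
  }
  mk <- function(assign) {
    v <- rep(0, 96)
    for (a in assign) v[a$i] <- v[a$i] + a$w
    v <- v + 0.10 / 96  # flat floor so no context has probability zero
    v / sum(v)
  }
  geo <- 0.88^(0:15)
  geo <- geo / sum(geo)
  bases <- c("A", "C", "G", "T")
  profiles <- cbind(
    SBS1 = mk(list(list(i = vapply(bases, function(f5) ctx(3L, f5, "G"),
                                   integer(1)), w = 0.85 / 4))),
    SBS2 = mk(list(list(i = vapply(bases, function(f3) ctx(3L, "T", f3),
                                   integer(1)), w = 0.85 / 4))),
    SBS3 = mk(list(list(i = c(block(2L), block(4L)), w = 0.62 / 32),
                   list(i = block(6L), w = 0.23 / 16))),
    SBS17a = mk(list(list(i = ctx(4L, "C", "T"), w = 0.60),
                     list(i = vapply(c("A", "G", "T"),
                                     function(f5) ctx(4L, f5, "T"),
                                     integer(1)), w = 0.25 / 3))),
    SBS17b = mk(list(list(i = ctx(6L, "C", "T"), w = 0.60),
                     list(i = vapply(c("A", "G", "T"),
                                     function(f5) ctx(6L, f5, "T"),
                                     integer(1)), w = 0.25 / 3))),
    SBS18 = mk(list(list(i = block(1L), w = 0.85 * geo))),
    SBS44 = mk(list(list(i = block(3L), w = 0.50 / 16),
                    list(i = block(5L), w = 0.35 / 16))),
    SBS52 = mk(list(list(i = vapply(bases, function(f3) ctx(1L, "T", f3),
                                    integer(1)), w = 0.85 / 4))))
  rownames(profiles) <- labels
  ref_panel(profiles, version = "synthetic-fixture-v1")
}

#' Configuration for the synthetic cohort generator
#'
#' The generator emulates the structure of a pooled gastric-cancer somatic
#' cohort: per-sample signature exposures drawn from a Dirichlet
#' distribution, Poisson mutation burdens with an optional hypermutator
#' subpopulation, gene labels drawn from a mutability panel (optionally
#' signature-biased to plant gene-level signal), and exponential survival
#' whose log hazard is linear in the true relative exposures and/or in true
#' per-(gene, signature) mutation counts, censored by an independent uniform
#' follow-up horizon.
#'
#' @param n_samples cohort size.
#' @param profiles 96 x K column-stochastic ground-truth profile matrix
#'   (default: the SBS1 / SBS18 / SBS44 columns of [make_fixture_panel()]).
#' @param exposure_alpha Dirichlet concentration, length K (default 1s).
#' @param mean_mutations Poisson mean SBS+indel burden per sample
#'   (default 300, a typical exome-scale load).
#' @param hypermut_fraction fraction of samples whose burden mean is
#'   multiplied by \code{hypermut_multiplier} (defaults 0.07 and 20,
#'   mirroring the roughly 7 percent hypermutated samples seen in gastric
#'   cohorts).
#' @param hypermut_multiplier burden multiplier for hypermutators.
#' @param indel_fraction probability a mutation is an indel rather than an
#'   SBS (default 0.1).
#' @param intergenic_fraction probability a mutation carries no gene symbol.
#' @param genes data.frame with \code{gene} and \code{weight} columns, the
#'   relative mutability panel (default: 40 genes with geometric weights).
#' @param gene_bias optional data.frame (\code{gene}, \code{signature},
#'   \code{bias}, optional \code{carrier_fraction}) multiplying a gene's
#'   weight for mutations truly generated by that signature — the device for
#'   planting informative (gene, signature) CCA features. When
#'   \code{carrier_fraction} < 1 the bias applies only in a random carrier
#'   subpopulation of that size (emulating, e.g., a repair-deficient
#'   subgroup that concentrates a signature's mutations in particular
#'   genes), which makes the planted feature bimodal across the cohort.
#' @param baseline_rate exponential baseline hazard per month (default
#'   log(2)/36: 36-month median survival at zero effect).
#' @param beta named per-signature log-hazard coefficients on true relative
#'   exposure (default all 0).
#' @param pair_effects optional data.frame (\code{gene}, \code{signature},
#'   \code{effect}): log-hazard per true mutation count in that gene from
#'   that signature (or per carrier when \code{pair_effect_scale} is
#'   \code{"carrier"}).
#' @param pair_effect_scale \code{"count"} (default): the log hazard is
#'   linear in the true per-pair mutation counts; \code{"carrier"}: the
#'   effect attaches to the underlying carrier state itself, the counts
#'   being its mutational readout — the natural model when a repair defect
#'   drives both the focal mutations and the outcome.
#' @param censor_horizon follow-up horizon in months; censoring times are
#'   uniform on (0, horizon) (default 120).
#' @param missing_clinical_fraction fraction of samples with unknown
#'   follow-up (group G4 fodder), default 0.1.
#' @param seed mandatory integer seed.
#' @return list of class \code{sim_config}.
#' @export
sim_config <- function(n_samples = 100,
                       profiles = NULL,
                       exposure_alpha = NULL,
                       mean_mutations = 300,
                       hypermut_fraction = 0.07,
                       hypermut_multiplier = 20,
                       indel_fraction = 0.1,
                       intergenic_fraction = 0.1,
                       genes = NULL,
                       gene_bias = NULL,
                       baseline_rate = log(2) / 36,
                       beta = NULL,
                       pair_effects = NULL,
                       pair_effect_scale = c("count", "carrier"),
                       censor_horizon = 120,
                       missing_clinical_fraction = 0.1,
                       seed) {
  if (missing(seed)) stop("a seed is mandatory for cohort simulation")
  if (is.null(profiles)) {
    panel <- make_fixture_panel()
    profiles <- panel$profiles[, c("SBS1", "SBS18", "SBS44")]
  }
  cs <- colSums(profiles)
  if (any(profiles < 0) || any(abs(cs - 1) > 1e-6)) {
    stop("ground-truth profiles must be column-stochastic")
  }
  K <- ncol(profiles)
  if (is.null(colnames(profiles))) colnames(profiles) <- paste0("T", 1:K)
  if (is.null(exposure_alpha)) exposure_alpha <- rep(1, K)
  stopifnot(length(exposure_alpha) == K, all(exposure_alpha > 0))
  if (is.null(genes)) {
    w <- 0.9^(0:39)
    genes <- data.frame(gene = sprintf("GENE%02d", 1:40), weight = w / sum(w),
                        stringsAsFactors = FALSE)
  }
  stopifnot(all(genes$weight > 0))
  if (is.null(beta)) beta <- stats::setNames(rep(0, K), colnames(profiles))
  structure(list(n_samples = n_samples, profiles = profiles,
                 exposure_alpha = exposure_alpha,
                 mean_mutations = mean_mutations,
                 hypermut_fraction = hypermut_fraction,
                 hypermut_multiplier = hypermut_multiplier,
                 indel_fraction = indel_fraction,
                 intergenic_fraction = intergenic_fraction,
                 genes = genes, gene_bias = gene_bias,
                 baseline_rate = baseline_rate, beta = beta,
                 pair_effects = pair_effects,
                 pair_effect_scale = match.arg(pair_effect_scale),
                 censor_horizon = censor_horizon,
                 missing_clinical_fraction = missing_clinical_fraction,
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Simulate a somatic mutation cohort with known ground truth
#'
#' For each sample: draw a true exposure vector from the Dirichlet; draw a
#' Poisson mutation count (inflated for hypermutators); for each mutation
#' draw its generating signature proportional to exposure, a 96-context
#' class from that signature's profile, and a gene from the mutability panel
#' (bias-adjusted for planted pairs); emit SBS records on a random strand
#' (so pyrimidine collapsing is exercised) and indels as multi-base records.
#' Survival times are exponential with log hazard linear in the configured
#' effects, censored by an independent uniform follow-up horizon; a fraction
#' of samples lose their clinical row entirely.
#'
#' @param config a [sim_config()].
#' @return list with \code{mutations} (mutation record table, plus
#'   \code{true_signature} column, empty for indels), \code{clinical}
#'   (clinical record table covering all samples; missing-information
#'   samples carry NA time and "unknown" status) and \code{truth} (list:
#'   \code{exposures} K x N true relative exposures, \code{profiles},
#'   \code{hypermutated}, \code{pair_counts} sample x "GENE|SIG" true counts
#'   for planted pairs, \code{hazard}).
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  old <- if (exists(".Random.seed", .GlobalEnv)) {
    get(".Random.seed", .GlobalEnv)
  }
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(config$seed)

  W <- config$profiles
  K <- ncol(W)
  sig_names <- colnames(W)
  n <- config$n_samples
  samples <- sprintf("SIM%03d", seq_len(n))
  labels <- sbs_class_labels()

  # true exposures: normalized gammas = Dirichlet
  g <- matrix(stats::rgamma(n * K, shape = config$exposure_alpha), K, n)
  expo <- sweep(g, 2, colSums(g), "/")
  dimnames(expo) <- list(sig_names, samples)

  hyper <- stats::runif(n) < config$hypermut_fraction
  mu <- config$mean_mutations * ifelse(hyper, config$hypermut_multiplier, 1)
  n_mut <- stats::rpois(n, mu)

  gene_w <- stats::setNames(config$genes$weight, config$genes$gene)
  bias <- config$gene_bias
  carriers <- NULL
  if (!is.null(bias)) {
    cf <- if ("carrier_fraction" %in% names(bias)) {
      bias$carrier_fraction
    } else {
      rep(1, nrow(bias))
    }
    carriers <- matrix(stats::runif(n * nrow(bias)) <
                         rep(cf, each = n), n, nrow(bias),
                       dimnames = list(samples,
                                       paste(bias$gene, bias$signature,
                                             sep = "|")))
  }

  recs <- vector("list", n)
  for (j in seq_len(n)) {
    m <- n_mut[j]
    if (m == 0L) {
      recs[[j]] <- NULL
      next
    }
    is_indel <- stats::runif(m) < config$indel_fraction
    sig <- sample(sig_names, m, replace = TRUE, prob = expo[, j])
    cls <- character(m)
    for (k in sig_names) {
      sel <- sig == k & !is_indel
      if (any(sel)) {
        cls[sel] <- sample(labels, sum(sel), replace = TRUE, prob = W[, k])
      }
    }
    gene <- character(m)
    for (k in sig_names) {
      sel <- sig == k
      if (!any(sel)) next
      w <- gene_w
      if (!is.null(bias)) {
        rows <- which(bias$signature == k & carriers[j, ])
        for (b in rows) w[bias$gene[b]] <- w[bias$gene[b]] * bias$bias[b]
      }
      gene[sel] <- sample(names(w), sum(sel), replace = TRUE, prob = w)
    }
    gene[stats::runif(m) < config$intergenic_fraction] <- ""

    parsed <- .parse_class(cls, is_indel)
    recs[[j]] <- data.frame(
      sample = samples[j],
      chrom = sample(paste0("chr", 1:22), m, replace = TRUE),
      pos = sample.int(5e7, m, replace = TRUE),
      ref = parsed$ref, alt = parsed$alt, gene = gene,
      flank5 = parsed$flank5, flank3 = parsed$flank3,
      variant_class = ifelse(is_indel, "INDEL", "SBS"),
      true_signature = ifelse(is_indel, "", sig),
      stringsAsFactors = FALSE)
  }
  mutations <- do.call(rbind, recs)
  rownames(mutations) <- NULL

  # true planted-pair counts per sample
  pair_counts <- NULL
  pairs <- config$pair_effects
  if (!is.null(pairs)) {
    pair_counts <- matrix(0, n, nrow(pairs),
                          dimnames = list(samples,
                                          paste(pairs$gene, pairs$signature,
                                                sep = "|")))
    sbs <- mutations[mutations$variant_class == "SBS", , drop = FALSE]
    for (i in seq_len(nrow(pairs))) {
      hit <- sbs$gene == pairs$gene[i] &
        sbs$true_signature == pairs$signature[i]
      tab <- table(factor(sbs$sample[hit], levels = samples))
      pair_counts[, i] <- as.numeric(tab)
    }
  }

  effect_basis <- pair_counts
  if (!is.null(pairs) && identical(config$pair_effect_scale, "carrier") &&
      !is.null(carriers)) {
    effect_basis <- 1 * carriers[, colnames(pair_counts), drop = FALSE]
  }
  clin <- simulate_clinical(
    exposures = expo, baseline_rate = config$baseline_rate,
    beta = config$beta, pair_counts = effect_basis,
    pair_effects = if (is.null(pairs)) NULL else stats::setNames(
      pairs$effect, paste(pairs$gene, pairs$signature, sep = "|")),
    censor_horizon = config$censor_horizon,
    missing_fraction = config$missing_clinical_fraction)

  list(mutations = mutations, clinical = clin$clinical,
       truth = list(exposures = expo, profiles = W, hypermutated = hyper,
                    pair_counts = pair_counts, carriers = carriers,
                    hazard = clin$hazard))
}

.parse_class <- function(cls, is_indel) {
  ref <- substr(cls, 3L, 3L)
  alt <- substr(cls, 5L, 5L)
  f5 <- substr(cls, 1L, 1L)
  f3 <- substr(cls, 7L, 7L)
  # emit roughly half the SBS records on the purine strand so that
  # classification has to collapse them back
  flip <- stats::runif(length(cls)) < 0.5 & !is_indel
  if (any(flip)) {
    r <- ref[flip]; a <- alt[flip]; p5 <- f5[flip]; p3 <- f3[flip]
    ref[flip] <- .complement[r]
    alt[flip] <- .complement[a]
    f5[flip] <- .complement[p3]
    f3[flip] <- .complement[p5]
  }
  if (any(is_indel)) {
    ref[is_indel] <- "A"
    alt[is_indel] <- "AT"
    f5[is_indel] <- NA_character_
    f3[is_indel] <- NA_character_
  }
  list(ref = ref, alt = alt, flank5 = f5, flank3 = f3)
}

#' Simulate survival outcomes given exposures
#'
#' Exponential survival with log hazard linear in true relative exposures
#' and, optionally, in planted per-(gene, signature) mutation counts;
#' censoring by an independent Uniform(0, horizon) follow-up time. Draws
#' from the current RNG stream unless \code{seed} is given.
#'
#' @param exposures K x N relative exposure matrix with sample columns.
#' @param baseline_rate exponential baseline hazard per month.
#' @param beta named per-signature log-hazard coefficients (default 0).
#' @param pair_counts optional samples x pairs count matrix.
#' @param pair_effects named log-hazard coefficients per pair column.
#' @param censor_horizon follow-up horizon in months.
#' @param missing_fraction fraction of samples reported with unknown
#'   follow-up.
#' @param seed optional integer seed.
#' @return list with \code{clinical} (data.frame sample, survival_months,
#'   event) and \code{hazard} (true per-sample hazard rates).
#' @export
simulate_clinical <- function(exposures, baseline_rate = log(2) / 36,
                              beta = NULL, pair_counts = NULL,
                              pair_effects = NULL, censor_horizon = 120,
                              missing_fraction = 0, seed = NULL) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", .GlobalEnv)) {
      get(".Random.seed", .GlobalEnv)
    }
    on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
    set.seed(seed)
  }
  samples <- colnames(exposures)
  n <- ncol(exposures)
  lp <- rep(0, n)
  if (!is.null(beta)) {
    beta <- beta[rownames(exposures)]
    beta[is.na(beta)] <- 0
    lp <- lp + as.numeric(crossprod(exposures, beta))
  }
  if (!is.null(pair_counts) && !is.null(pair_effects)) {
    eff <- pair_effects[colnames(pair_counts)]
    eff[is.na(eff)] <- 0
    lp <- lp + as.numeric(pair_counts %*% eff)
  }
  rate <- baseline_rate * exp(lp)
  t_event <- stats::rexp(n, rate)
  t_cens <- stats::runif(n, 0, censor_horizon)
  time <- pmin(t_event, t_cens)
  event <- ifelse(t_event <= t_cens, "dead", "alive")
  missing <- stats::runif(n) < missing_fraction
  time[missing] <- NA_real_
  event[missing] <- "unknown"
  list(clinical = data.frame(sample = samples, survival_months = time,
                             event = event, stringsAsFactors = FALSE),
       hazard = stats::setNames(rate, samples))
}
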