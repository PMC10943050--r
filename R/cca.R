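#' Posterior signature attribution of individual mutations
#'
#' For a mutation of 96-context class c in sample j, the probability that
#' signature k generated it is proportional to W[c, k] * H[k, j] — the
#' product of the signature's propensity for that context and the sample's
#' exposure to the signature — normalized over signatures. Mutations whose
#' candidate products are all zero fall back to a uniform posterior over the
#' sample's active (nonzero-exposure) signatures, with a warning.
#'
#' @param records mutation record table (see [mutation_records()]); only SBS
#'   records with valid bases receive posteriors.
#' @param fit a \code{sig_nmf}, or a list with elements \code{signatures}
#'   (96 x K column-stochastic) and \code{exposures} (K x N with sample
#'   columns).
#' @return data.frame with one row per attributable SBS record: the record
#'   columns \code{sample}, \code{gene}, \code{class}, plus one posterior
#'   column per signature. Posteriors in each row sum to 1.
#' @export
attribute_mutations <- function(records, fit) {
  records <- mutation_records(records)
  W <- fit$signatures
  H <- fit$exposures
  stopifnot(!is.null(colnames(H)), !is.null(colnames(W)))
  sbs <- records[records$variant_class == "SBS", , drop = FALSE]
  ok <- sbs$ref %in% c("A", "C", "G", "T") &
    sbs$alt %in% c("A", "C", "G", "T") &
    sbs$flank5 %in% c("A", "C", "G", "T") &
    sbs$flank3 %in% c("A", "C", "G", "T") &
    sbs$sample %in% colnames(H)
  sbs <- sbs[ok, , drop = FALSE]
  if (nrow(sbs) == 0L) stop("no attributable SBS records")
  cls <- classify_substitution(sbs$ref, sbs$alt, sbs$flank5, sbs$flank3)

  K <- ncol(W)
  raw <- W[cls, , drop = FALSE] * t(H)[sbs$sample, , drop = FALSE]
  tot <- rowSums(raw)
  degenerate <- tot == 0
  if (any(degenerate)) {
    warning(sprintf(
      "%d mutation(s) had zero posterior mass; using uniform over active signatures",
      sum(degenerate)))
    for (i in which(degenerate)) {
      active <- H[, sbs$sample[i]] > 0
      if (!any(active)) active <- rep(TRUE, K)
      raw[i, ] <- as.numeric(active) / sum(active)
    }
    tot <- rowSums(raw)
  }
  post <- raw / tot
  colnames(post) <- colnames(W)
  out <- data.frame(sample = sbs$sample, gene = sbs$gene, class = cls,
                    stringsAsFactors = FALSE)
  cbind(out, as.data.frame(post, optional = TRUE))
}

#' Cumulative contribution abundance (CCA) per sample, gene and signature
#'
#' The CCA of gene g on signature k in sample j is the sum, over the
#' sample's gene-annotated SBS mutations in g, of the posterior probability
#' that signature k generated each mutation — the expected number of the
#' gene's mutations attributable to the signature. Records with an empty
#' gene symbol are excluded. Totalled over genes and signatures, each
#' sample's CCA mass equals its count of gene-annotated SBS mutations.
#'
#' @param attributions result of [attribute_mutations()].
#' @param signatures signature names to keep (default: all in the
#'   attribution table). Unknown names raise an error listing those
#'   available.
#' @param normalize if TRUE, each sample's scores are divided by its total
#'   attributed mutation count (default FALSE: raw cumulative counts).
#' @return An object of class \code{cca_table}: a long-format data.frame
#'   with \code{sample}, \code{gene}, \code{signature}, \code{cca}, plus
#'   attributes \code{samples} (all samples seen) and \code{normalized}.
#' @export
compute_cca <- function(attributions, signatures = NULL, normalize = FALSE) {
  meta <- c("sample", "gene", "class")
  sigs_avail <- setdiff(names(attributions), meta)
  if (is.null(signatures)) signatures <- sigs_avail
  unknown <- setdiff(signatures, sigs_avail)
  if (length(unknown)) {
    stop("unknown signature(s) ", paste(unknown, collapse = ", "),
         "; available: ", paste(sigs_avail, collapse = ", "))
  }
  ann <- attributions[attributions$gene != "", , drop = FALSE]
  pieces <- lapply(signatures, function(s) {
    agg <- stats::aggregate(ann[[s]],
                            by = list(sample = ann$sample, gene = ann$gene),
                            FUN = sum)
    data.frame(sample = agg$sample, gene = agg$gene, signature = s,
               cca = agg$x, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, pieces)
  out <- out[order(out$sample, out$gene, out$signature), , drop = FALSE]
  rownames(out) <- NULL
  if (normalize) {
    tot <- tapply(out$cca, out$sample, sum)
    denom <- as.numeric(tot[out$sample])
    out$cca <- ifelse(denom > 0, out$cca / denom, 0)
  }
  structure(out,
            samples = unique(attributions$sample),
            normalized = normalize,
            class = c("cca_table", "data.frame"))
}

#' Dense feature matrix of CCA scores
#'
#' Expands a CCA table to a samples x features numeric matrix with feature
#' names \code{"GENE|SIG"}; (gene, signature) pairs absent from a sample are
#' zero-filled, and requested genes/signatures never seen at all yield
#' all-zero columns (kept, not dropped).
#'
#' @param table a \code{cca_table}.
#' @param genes gene symbols defining the column blocks (default: all genes
#'   present, sorted).
#' @param signatures signature names within each gene block (default: all
#'   present, in table order).
#' @param samples row order (default: all samples the attributions covered).
#' @return numeric matrix, rows = samples, columns = \code{"GENE|SIG"} in
#'   the given gene-major order.
#' @export
cca_feature_matrix <- function(table, genes = NULL, signatures = NULL,
                               samples = NULL) {
  stopifnot(inherits(table, "cca_table"))
  if (is.null(genes)) genes <- sort(unique(table$gene))
  if (is.null(signatures)) signatures <- unique(table$signature)
  if (is.null(samples)) samples <- attr(table, "samples")
  feats <- as.vector(t(outer(genes, signatures, paste, sep = "|")))
  m <- matrix(0, nrow = length(samples), ncol = length(feats),
              dimnames = list(samples, feats))
  key <- paste(table$gene, table$signature, sep = "|")
  keep <- key %in% feats & table$sample %in% samples
  sub <- table[keep, , drop = FALSE]
  if (nrow(sub)) {
    m[cbind(match(sub$sample, samples),
            match(key[keep], feats))] <- sub$cca
  }
  m
}

#' Write a CCA table and its feature matrix
#'
#' @param table a \code{cca_table}.
#' @param prefix output prefix; writes \code{<prefix>.cca.tsv} (long format)
#'   and \code{<prefix>.cca.matrix.tsv} (wide feature matrix).
#' @export
write_cca <- function(table, prefix) {
  utils::write.table(as.data.frame(table), paste0(prefix, ".cca.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  m <- cca_feature_matrix(table)
  df <- data.frame(sample = rownames(m), m, check.names = FALSE)
  utils::write.table(df, paste0(prefix, ".cca.matrix.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(prefix)
}
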