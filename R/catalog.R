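#' Assemble a somatic mutation record table
#'
#' Normalises a data.frame of somatic variants into the column layout the
#' rest of the pipeline consumes. Coordinates are 1-based inclusive (MAF
#' convention); strand is assumed "+" — pyrimidine collapsing is handled at
#' classification time, never via input strand fields.
#'
#' @param df data.frame with columns \code{sample}, \code{chrom}, \code{pos},
#'   \code{ref}, \code{alt}, \code{gene}, \code{flank5}, \code{flank3},
#'   \code{variant_class} ("SBS" or "INDEL"). Missing \code{gene} entries may
#'   be empty strings or NA. Flanks may be NA for INDEL records.
#' @return The validated data.frame with columns in canonical order.
#' @export
mutation_records <- function(df) {
  needed <- c("sample", "chrom", "pos", "ref", "alt", "gene",
              "flank5", "flank3", "variant_class")
  missing <- setdiff(needed, names(df))
  if (length(missing)) {
    stop("mutation record table lacks column(s): ",
         paste(missing, collapse = ", "))
  }
  df <- df[, needed]
  df$sample <- as.character(df$sample)
  df$chrom <- as.character(df$chrom)
  df$pos <- as.integer(df$pos)
  for (col in c("ref", "alt", "flank5", "flank3")) {
    df[[col]] <- toupper(as.character(df[[col]]))
  }
  df$gene <- as.character(df$gene)
  df$gene[is.na(df$gene)] <- ""
  df$variant_class <- as.character(df$variant_class)
  if (!all(df$variant_class %in% c("SBS", "INDEL"))) {
    stop("variant_class must be 'SBS' or 'INDEL'")
  }
  if (any(df$ref == df$alt, na.rm = TRUE)) {
    stop("record(s) with ref == alt are not variants")
  }
  df
}

#' Build a 96-context mutation catalog from somatic records
#'
#' Tallies each sample's single-base substitutions into the 96
#' trinucleotide-context classes. INDEL records are excluded from the
#' 96-class matrix but counted toward per-sample mutation totals (used for
#' hypermutation flagging). SBS records whose reference, alternate or
#' flanking bases are not single A/C/G/T characters (e.g. N flanks,
#' multi-base MNV alleles) are skipped with a warning and reported in the
#' returned skip count.
#'
#' @param records mutation record table (see [mutation_records()]).
#' @return An object of class \code{mut_catalog}: a list with
#'   \describe{
#'     \item{counts}{samples x 96 integer matrix, rows in first-occurrence
#'       sample order, columns in [sbs_class_labels()] order.}
#'     \item{totals}{named per-sample totals including INDELs.}
#'     \item{n_skipped}{number of SBS records skipped for invalid bases.}
#'   }
#' @export
build_catalog <- function(records) {
  records <- mutation_records(records)
  if (nrow(records) == 0L) stop("no mutation records supplied")
  samples <- unique(records$sample)
  labels <- sbs_class_labels()
  counts <- matrix(0L, nrow = length(samples), ncol = 96L,
                   dimnames = list(samples, labels))

  totals <- vapply(samples, function(s) sum(records$sample == s), integer(1))

  sbs <- records[records$variant_class == "SBS", , drop = FALSE]
  single <- function(x) !is.na(x) & x %in% c("A", "C", "G", "T")
  ok <- single(sbs$ref) & single(sbs$alt) &
    single(sbs$flank5) & single(sbs$flank3)
  n_skipped <- sum(!ok)
  if (n_skipped > 0L) {
    warning(sprintf(
      "skipped %d SBS record(s) with non-ACGT or multi-base alleles/flanks",
      n_skipped))
  }
  sbs <- sbs[ok, , drop = FALSE]
  if (nrow(sbs) > 0L) {
    cls <- classify_substitution(sbs$ref, sbs$alt, sbs$flank5, sbs$flank3)
    tab <- table(factor(sbs$sample, levels = samples),
                 factor(cls, levels = labels))
    counts[] <- as.integer(tab)
  }
  structure(list(counts = counts, totals = totals, n_skipped = n_skipped),
            class = "mut_catalog")
}

#' @export
print.mut_catalog <- function(x, ...) {
  cat(sprintf("96-context SBS catalog: %d sample(s), %d substitutions",
              nrow(x$counts), sum(x$counts)))
  if (x$n_skipped > 0) cat(sprintf(" (%d records skipped)", x$n_skipped))
  cat("\n")
  props <- tryCatch(category_proportions(x), error = function(e) NULL)
  if (!is.null(props)) {
    cat("substitution class proportions:\n")
    print(round(props, 3))
  }
  invisible(x)
}

#' @export
summary.mut_catalog <- function(object, ...) {
  cat(sprintf("samples: %d\n", nrow(object$counts)))
  cat("per-sample SBS counts:\n")
  print(summary(rowSums(object$counts)))
  cat("per-sample total mutations (incl. indels):\n")
  print(summary(as.numeric(object$totals)))
  invisible(object)
}

#' Lego-style barplot of a catalog's pooled 96-class spectrum
#'
#' @param x a \code{mut_catalog}.
#' @param ... passed to [graphics::barplot()].
#' @export
plot.mut_catalog <- function(x, ...) {
  pooled <- colSums(x$counts)
  cols <- rep(c("#03BCEE", "#010101", "#E32926",
                "#CAC9C9", "#A1CE63", "#EBC6C4"), each = 16L)
  graphics::barplot(pooled, col = cols, border = NA, las = 2,
                    cex.names = 0.35, ylab = "mutation count", ...)
  invisible(x)
}

#' Flag hypermutated samples
#'
#' A sample is hypermutated when its total somatic mutation burden (SBS plus
#' indel) exceeds a threshold. The threshold defaults to 1000 mutations per
#' sample, the usual exome-scale convention; it is fully configurable.
#'
#' @param catalog a \code{mut_catalog}, or NULL when \code{totals} is given.
#' @param totals optional named per-sample totals overriding the catalog's.
#' @param threshold positive integer burden cutoff (strict ">").
#' @return data.frame with \code{sample}, \code{total_mutations},
#'   \code{is_hypermutated}.
#' @export
flag_hypermutated <- function(catalog = NULL, totals = NULL, threshold = 1000) {
  stopifnot(threshold > 0)
  if (is.null(totals)) {
    stopifnot(inherits(catalog, "mut_catalog"))
    totals <- catalog$totals
  }
  data.frame(sample = names(totals),
             total_mutations = as.integer(totals),
             is_hypermutated = as.integer(totals) > threshold,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Proportion of the six substitution classes in a catalog
#'
#' @param catalog a \code{mut_catalog}.
#' @return Named numeric vector over the six substitution types, summing to 1.
#' @export
category_proportions <- function(catalog) {
  stopifnot(inherits(catalog, "mut_catalog"))
  pooled <- colSums(catalog$counts)
  total <- sum(pooled)
  if (total == 0) stop("all-zero catalog: proportions undefined")
  type <- rep(sbs_substitution_types(), each = 16L)
  out <- tapply(pooled, type, sum) / total
  c(out[sbs_substitution_types()])
}

#' Read a MAF-like somatic mutation TSV
#'
#' Requires the columns Tumor_Sample_Barcode, Chromosome, Start_Position,
#' Reference_Allele, Tumor_Seq_Allele2, Hugo_Symbol and Variant_Type.
#' Flanking bases for SBS records are taken from, in order of preference:
#' explicit \code{flank5}/\code{flank3} columns; a \code{context} or
#' \code{ref_context} column (either \code{"X[R>Y]Z"} notation or an
#' odd-length sequence centred on the variant base); or a genome FASTA
#' (requires the Rsamtools package).
#'
#' @param path path to the TSV file.
#' @param fasta optional path to an indexed genome FASTA used to derive
#'   flanking bases when the file carries none.
#' @return A mutation record table (see [mutation_records()]).
#' @export
read_maf <- function(path, fasta = NULL) {
  maf <- utils::read.delim(path, stringsAsFactors = FALSE,
                           check.names = FALSE, comment.char = "#")
  needed <- c("Tumor_Sample_Barcode", "Chromosome", "Start_Position",
              "Reference_Allele", "Tumor_Seq_Allele2", "Hugo_Symbol",
              "Variant_Type")
  missing <- setdiff(needed, names(maf))
  if (length(missing)) {
    stop("MAF lacks required column(s): ", paste(missing, collapse = ", "))
  }
  vt <- toupper(maf$Variant_Type)
  variant_class <- ifelse(vt %in% c("SNP", "SNV", "SBS"), "SBS",
                          ifelse(vt %in% c("INS", "DEL", "INDEL"),
                                 "INDEL", NA))
  if (anyNA(variant_class)) {
    warning(sprintf("dropping %d record(s) with unsupported Variant_Type",
                    sum(is.na(variant_class))))
    keep <- !is.na(variant_class)
    maf <- maf[keep, , drop = FALSE]
    variant_class <- variant_class[keep]
  }

  flank5 <- rep(NA_character_, nrow(maf))
  flank3 <- rep(NA_character_, nrow(maf))
  if (all(c("flank5", "flank3") %in% names(maf))) {
    flank5 <- toupper(as.character(maf$flank5))
    flank3 <- toupper(as.character(maf$flank3))
  } else {
    ctx_col <- intersect(c("context", "ref_context"), names(maf))[1]
    if (!is.na(ctx_col)) {
      fl <- .flanks_from_context(as.character(maf[[ctx_col]]))
      flank5 <- fl$flank5
      flank3 <- fl$flank3
    } else if (!is.null(fasta)) {
      fl <- .flanks_from_fasta(fasta, maf$Chromosome,
                               as.integer(maf$Start_Position))
      flank5 <- fl$flank5
      flank3 <- fl$flank3
    }
  }

  mutation_records(data.frame(
    sample = maf$Tumor_Sample_Barcode,
    chrom = maf$Chromosome,
    pos = as.integer(maf$Start_Position),
    ref = maf$Reference_Allele,
    alt = maf$Tumor_Seq_Allele2,
    gene = maf$Hugo_Symbol,
    flank5 = flank5,
    flank3 = flank3,
    variant_class = variant_class,
    stringsAsFactors = FALSE))
}

.flanks_from_context <- function(ctx) {
  ctx <- toupper(ctx)
  n <- length(ctx)
  f5 <- rep(NA_character_, n)
  f3 <- rep(NA_character_, n)
  bracket <- grepl("^[ACGTN]\\[[ACGT]>[ACGT]\\][ACGTN]$", ctx)
  f5[bracket] <- substr(ctx[bracket], 1L, 1L)
  f3[bracket] <- substr(ctx[bracket], 7L, 7L)
  plain <- !bracket & !is.na(ctx) & grepl("^[ACGTN]+$", ctx) &
    nchar(ctx) %% 2L == 1L & nchar(ctx) >= 3L
  mid <- (nchar(ctx[plain]) + 1L) %/% 2L
  f5[plain] <- substr(ctx[plain], mid - 1L, mid - 1L)
  f3[plain] <- substr(ctx[plain], mid + 1L, mid + 1L)
  list(flank5 = f5, flank3 = f3)
}

.flanks_from_fasta <- function(fasta, chrom, pos) {
  if (!requireNamespace("Rsamtools", quietly = TRUE)) {
    stop("deriving flanks from a FASTA requires the Rsamtools package")
  }
  fa <- Rsamtools::FaFile(fasta)
  gr <- GenomicRanges::GRanges(chrom,
                               IRanges::IRanges(pos - 1L, pos + 1L))
  seqs <- as.character(Rsamtools::scanFa(fa, gr))
  list(flank5 = substr(seqs, 1L, 1L), flank3 = substr(seqs, 3L, 3L))
}

#' Write / read a catalog in the COSMIC layout
#'
#' The COSMIC catalog layout has a first column \code{MutationType} holding
#' the 96 class labels and one column per sample. \code{transpose = TRUE}
#' writes samples as rows instead.
#'
#' @param catalog a \code{mut_catalog}.
#' @param path output TSV path.
#' @param transpose write samples as rows.
#' @export
write_catalog <- function(catalog, path, transpose = FALSE) {
  stopifnot(inherits(catalog, "mut_catalog"))
  m <- t(catalog$counts)
  if (transpose) {
    df <- data.frame(Sample = rownames(catalog$counts),
                     catalog$counts, check.names = FALSE)
  } else {
    df <- data.frame(MutationType = rownames(m), m, check.names = FALSE)
  }
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_catalog
#' @export
read_catalog <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  labels <- sbs_class_labels()
  if (identical(names(df)[1], "MutationType")) {
    rn <- df$MutationType
    m <- as.matrix(df[, -1, drop = FALSE])
    rownames(m) <- rn
    if (!setequal(rn, labels)) stop("catalog rows are not the 96 SBS classes")
    counts <- t(m[labels, , drop = FALSE])
  } else {
    rn <- df[[1]]
    m <- as.matrix(df[, -1, drop = FALSE])
    rownames(m) <- rn
    if (!setequal(colnames(m), labels)) {
      stop("catalog columns are not the 96 SBS classes")
    }
    counts <- m[, labels, drop = FALSE]
  }
  storage.mode(counts) <- "integer"
  structure(list(counts = counts,
                 totals = stats::setNames(rowSums(counts), rownames(counts)),
                 n_skipped = 0L),
            class = "mut_catalog")
}

#' Construct a catalog directly from a counts matrix
#'
#' @param counts samples x 96 non-negative matrix with the class labels as
#'   column names (any order; reordered internally).
#' @param totals optional per-sample totals including indels; defaults to the
#'   SBS row sums.
#' @return A \code{mut_catalog}.
#' @export
as_catalog <- function(counts, totals = NULL) {
  labels <- sbs_class_labels()
  if (is.null(colnames(counts)) || !setequal(colnames(counts), labels)) {
    stop("counts must have the 96 SBS class labels as column names")
  }
  counts <- counts[, labels, drop = FALSE]
  if (any(counts < 0)) stop("negative counts")
  if (is.null(rownames(counts))) {
    rownames(counts) <- paste0("sample", seq_len(nrow(counts)))
  }
  if (is.null(totals)) {
    totals <- stats::setNames(rowSums(counts), rownames(counts))
  }
  structure(list(counts = counts, totals = totals, n_skipped = 0L),
            class = "mut_catalog")
}
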