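#' The 96 single-base-substitution context classes
#'
#' Somatic single-base substitutions are conventionally collapsed onto the
#' pyrimidine strand and classified by substitution type (C>A, C>G, C>T,
#' T>A, T>C, T>G) together with the bases immediately 5' and 3' of the
#' mutated base, giving 6 x 4 x 4 = 96 classes written \code{"A[C>T]G"}.
#'
#' @return Character vector of the 96 class labels, ordered by substitution
#'   type, then 5' flank, then 3' flank (the COSMIC catalog order).
#' @examples
#' head(sbs_class_labels())
#' @export
sbs_class_labels <- function() {
  bases <- c("A", "C", "G", "T")
  labs <- character(0)
  for (type in sbs_substitution_types()) {
    for (f5 in bases) {
      for (f3 in bases) {
        labs <- c(labs, paste0(f5, "[", type, "]", f3))
      }
    }
  }
  labs
}

#' The six pyrimidine substitution types
#'
#' @return Character vector \code{c("C>A","C>G","C>T","T>A","T>C","T>G")}.
#' @export
sbs_substitution_types <- function() {
  c("C>A", "C>G", "C>T", "T>A", "T>C", "T>G")
}

.complement <- c(A = "T", C = "G", G = "C", T = "A")

#' Classify a single-base substitution into its 96-context class
#'
#' Purine-reference substitutions (A or G reference) are reverse-complemented
#' together with both flanking bases before labelling, so every substitution
#' maps onto a pyrimidine-reference class. Vectorised over all arguments.
#'
#' @param ref reference base(s), one of A/C/G/T.
#' @param alt alternate base(s), one of A/C/G/T, different from \code{ref}.
#' @param flank5 base immediately 5' of the substitution.
#' @param flank3 base immediately 3' of the substitution.
#' @return Character vector of class labels such as \code{"T[C>A]G"}.
#' @examples
#' classify_substitution("C", "A", "A", "A")  # "A[C>A]A"
#' classify_substitution("G", "A", "T", "C")  # "G[C>T]A"
#' @export
classify_substitution <- function(ref, alt, flank5, flank3) {
  n <- max(length(ref), length(alt), length(flank5), length(flank3))
  ref <- toupper(rep_len(as.character(ref), n))
  alt <- toupper(rep_len(as.character(alt), n))
  flank5 <- toupper(rep_len(as.character(flank5), n))
  flank3 <- toupper(rep_len(as.character(flank3), n))

  bases <- c("A", "C", "G", "T")
  bad <- !(ref %in% bases) | !(alt %in% bases) |
    !(flank5 %in% bases) | !(flank3 %in% bases)
  if (any(bad)) {
    stop("non-ACGT base in substitution at position(s): ",
         paste(utils::head(which(bad), 5L), collapse = ", "))
  }
  if (any(ref == alt)) {
    stop("ref == alt is not a substitution at position(s): ",
         paste(utils::head(which(ref == alt), 5L), collapse = ", "))
  }

  purine <- ref %in% c("A", "G")
  if (any(purine)) {
    r <- ref[purine]; a <- alt[purine]
    f5 <- flank5[purine]; f3 <- flank3[purine]
    ref[purine] <- .complement[r]
    alt[purine] <- .complement[a]
    # reverse complement swaps the flanks
    flank5[purine] <- .complement[f3]
    flank3[purine] <- .complement[f5]
  }
  paste0(flank5, "[", ref, ">", alt, "]", flank3)
}
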