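#' Cosine similarity between two non-negative 96-class profiles
#'
#' @param a,b numeric vectors of equal length with nonzero norm.
#' @return Scalar in [0, 1] for non-negative inputs; symmetric and invariant
#'   to positive rescaling of either argument.
#' @export
cosine_similarity <- function(a, b) {
  stopifnot(length(a) == length(b))
  na <- sqrt(sum(a^2))
  nb <- sqrt(sum(b^2))
  if (na == 0 || nb == 0) stop("cosine similarity undefined for zero vector")
  sum(a * b) / (na * nb)
}

#' Read a COSMIC-layout reference signature panel
#'
#' Expects a TSV with a \code{Type} column holding the 96 class labels
#' (\code{"A[C>A]A"} style) and one column per reference signature.
#'
#' @param path TSV path.
#' @param version free-text panel version tag stored on the result.
#' @return A list of class \code{ref_panel}: \code{profiles} (96 x M matrix,
#'   rows in [sbs_class_labels()] order, columns renormalized to sum to 1),
#'   \code{names}, \code{version}.
#' @export
read_ref_panel <- function(path, version = basename(path)) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  type_col <- intersect(c("Type", "MutationType"), names(df))[1]
  if (is.na(type_col)) stop("panel needs a 'Type' or 'MutationType' column")
  m <- as.matrix(df[, setdiff(names(df), type_col), drop = FALSE])
  rownames(m) <- df[[type_col]]
  ref_panel(m, version = version)
}

#' Construct a reference panel from a profile matrix
#'
#' @param profiles 96 x M non-negative matrix, rows named by class label.
#' @param version free-text version tag.
#' @return A \code{ref_panel}.
#' @export
ref_panel <- function(profiles, version = "custom") {
  labels <- sbs_class_labels()
  if (is.null(rownames(profiles)) || !setequal(rownames(profiles), labels)) {
    stop("panel rows must be the 96 SBS class labels")
  }
  profiles <- profiles[labels, , drop = FALSE]
  if (any(profiles < 0)) stop("negative panel entries")
  cs <- colSums(profiles)
  if (any(cs == 0)) stop("all-zero panel column")
  profiles <- sweep(profiles, 2, cs, "/")
  structure(list(profiles = profiles, names = colnames(profiles),
                 version = version),
            class = "ref_panel")
}

#' @export
print.ref_panel <- function(x, ...) {
  cat(sprintf("reference signature panel '%s': %d profiles\n",
              x$version, length(x$names)))
  cat(paste(x$names, collapse = ", "), "\n")
  invisible(x)
}

#' Name extracted signatures against a reference panel
#'
#' Each extracted signature is assigned the reference profile with the
#' highest cosine similarity; the assigned name is the reference name with a
#' trailing \code{"*"}, marking it as a de-novo extraction matched to that
#' reference. Matches below \code{min_cosine} keep their provisional name
#' and are flagged \code{novel}. When two extracted signatures hit the same
#' reference both matches are reported and flagged as a collision. Exact
#' cosine ties are broken by lexicographic reference name (logged).
#'
#' @param signatures a \code{sig_nmf} fit or a 96 x K column matrix with
#'   class-label rownames.
#' @param panel a \code{ref_panel}.
#' @param min_cosine minimum cosine for a named match (default 0.80).
#' @return data.frame with \code{extracted_id}, \code{reference_name},
#'   \code{cosine}, \code{assigned_name}, \code{novel}, \code{collision}.
#' @export
match_panel <- function(signatures, panel, min_cosine = 0.80) {
  if (inherits(signatures, "sig_nmf")) signatures <- signatures$signatures
  stopifnot(inherits(panel, "ref_panel"))
  labels <- sbs_class_labels()
  if (is.null(rownames(signatures)) ||
      !setequal(rownames(signatures), labels)) {
    stop("signature rows must be the 96 SBS class labels")
  }
  signatures <- signatures[labels, , drop = FALSE]
  ids <- colnames(signatures)
  if (is.null(ids)) ids <- paste0("S", seq_len(ncol(signatures)))

  pn <- panel$names
  res <- lapply(seq_len(ncol(signatures)), function(j) {
    cs <- vapply(pn, function(nm) {
      cosine_similarity(signatures[, j], panel$profiles[, nm])
    }, numeric(1))
    best <- max(cs)
    cand <- pn[cs == best]
    if (length(cand) > 1L) {
      message(sprintf("cosine tie for %s broken lexicographically (%s)",
                      ids[j], paste(sort(cand), collapse = ", ")))
    }
    nm <- sort(cand)[1]
    data.frame(extracted_id = ids[j], reference_name = nm,
               cosine = best, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$novel <- out$cosine < min_cosine
  out$assigned_name <- ifelse(out$novel, out$extracted_id,
                              paste0(out$reference_name, "*"))
  dup <- out$reference_name[!out$novel]
  out$collision <- !out$novel &
    out$reference_name %in% dup[duplicated(dup)]
  out[, c("extracted_id", "reference_name", "cosine", "assigned_name",
          "novel", "collision")]
}

#' Rename a signature fit by its panel matches
#'
#' Applies the assigned names from [match_panel()] (e.g. \code{"SBS44*"})
#' to the signature, exposure and relative-exposure matrices of a
#' \code{sig_nmf} fit, so downstream attribution and survival analyses can
#' refer to signatures by their reference names.
#'
#' @param fit a \code{sig_nmf}.
#' @param matches result of [match_panel()] for that fit.
#' @return The fit with renamed signature dimensions.
#' @export
apply_matches <- function(fit, matches) {
  stopifnot(inherits(fit, "sig_nmf"),
            identical(matches$extracted_id, colnames(fit$signatures)))
  colnames(fit$signatures) <- matches$assigned_name
  rownames(fit$exposures) <- matches$assigned_name
  rownames(fit$relative) <- matches$assigned_name
  fit
}

#' Write a signature match table
#'
#' @param matches result of [match_panel()].
#' @param path output TSV path.
#' @export
write_matches <- function(matches, path) {
  utils::write.table(matches, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
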