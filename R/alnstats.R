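#' Classify alignment columns
#'
#' A column is *complete* iff no sequence has a gap or `N` there; a complete
#' column is *polymorphic* iff at least two distinct bases occur in it.
#' Columns with any gap or missing data are excluded from polymorphism
#' counting entirely (complete deletion), matching the convention of
#' reporting "sites without gaps or missing data" and counting segregating
#' sites among those.
#'
#' @param aln A [build_alignment()] object.
#' @return A list with `n_sites`, `n_complete`, `n_polymorphic`.
#' @export
classify_sites <- function(aln) {
  stopifnot(inherits(aln, "barcode_alignment"))
  comp <- complete_columns(aln)
  poly <- vapply(which(comp), function(j)
    length(unique(aln$mat[, j])) >= 2L, logical(1))
  list(n_sites = aln$n_sites, n_complete = sum(comp),
       n_polymorphic = sum(poly))
}

# logical vector: column has no '-' or 'N' in any sequence
complete_columns <- function(aln) {
  colSums(aln$mat == "-" | aln$mat == "N") == 0L
}

#' Nucleotide diversity (pi)
#'
#' Mean over all unordered sequence pairs of the per-site proportion of
#' differences, computed over complete-deletion columns so every pair shares
#' the same denominator.
#'
#' @param aln A [build_alignment()] object with at least 2 sequences.
#' @return Per-site nucleotide diversity (dimensionless).
#' @export
nucleotide_diversity <- function(aln) {
  stopifnot(inherits(aln, "barcode_alignment"))
  comp <- which(complete_columns(aln))
  if (length(comp) == 0L) stop("no complete columns: pi undefined")
  m <- aln$mat[, comp, drop = FALSE]
  n <- nrow(m)
  diffs <- 0
  for (i in seq_len(n - 1L))
    for (j in (i + 1L):n)
      diffs <- diffs + sum(m[i, ] != m[j, ])
  diffs / (n * (n - 1L) / 2) / length(comp)
}

#' Average base composition
#'
#' Per-sequence frequencies of T, C, A, G over scoreable bases only (gaps
#' and `N` excluded from the denominator), then averaged across sequences —
#' the convention under which a reported mean AT content is well defined
#' even when sequences have unequal amounts of missing data.
#'
#' @param aln A [build_alignment()] object.
#' @return A list with `freq_T`, `freq_C`, `freq_A`, `freq_G`, `at_content`.
#' @export
base_composition <- function(aln) {
  stopifnot(inherits(aln, "barcode_alignment"))
  per_seq <- t(apply(aln$mat, 1L, function(row) {
    row <- row[row %in% c("A", "C", "G", "T")]
    if (length(row) == 0L) return(rep(NA_real_, 4L))
    c(T = sum(row == "T"), C = sum(row == "C"),
      A = sum(row == "A"), G = sum(row == "G")) / length(row)
  }))
  if (anyNA(per_seq)) {
    bad <- aln$ids[apply(per_seq, 1L, anyNA)]
    stop("sequence(s) with no scoreable bases: ", paste(bad, collapse = ", "))
  }
  f <- colMeans(per_seq)
  list(freq_T = f[["T"]], freq_C = f[["C"]], freq_A = f[["A"]],
       freq_G = f[["G"]], at_content = f[["A"]] + f[["T"]])
}

#' Count haplotypes
#'
#' Number of distinct sequences after projection onto complete-deletion
#' columns.
#'
#' @param aln A [build_alignment()] object.
#' @return Integer haplotype count.
#' @export
count_haplotypes <- function(aln) {
  stopifnot(inherits(aln, "barcode_alignment"))
  comp <- complete_columns(aln)
  m <- aln$mat[, comp, drop = FALSE]
  length(unique(apply(m, 1L, paste, collapse = "")))
}

#' Full alignment summary
#'
#' @param aln A [build_alignment()] object.
#' @return A list of class `alignment_summary` combining [classify_sites()],
#'   [nucleotide_diversity()], [base_composition()] and
#'   [count_haplotypes()].
#' @export
alignment_summary <- function(aln) {
  cs <- classify_sites(aln)
  bc <- base_composition(aln)
  structure(c(cs, list(pi = nucleotide_diversity(aln)), bc,
              list(n_haplotypes = count_haplotypes(aln))),
            class = "alignment_summary")
}

#' @export
print.alignment_summary <- function(x, ...) {
  cat("Sites: ", x$n_sites, " total, ", x$n_complete,
      " complete, ", x$n_polymorphic, " polymorphic (",
      sprintf("%.1f%%", 100 * x$n_polymorphic / x$n_complete), ")\n",
      sep = "")
  cat(sprintf("Nucleotide diversity (pi): %.4f\n", x$pi))
  cat(sprintf("Base composition: T=%.1f%% C=%.1f%% A=%.1f%% G=%.1f%% (AT=%.1f%%)\n",
              100 * x$freq_T, 100 * x$freq_C, 100 * x$freq_A, 100 * x$freq_G,
              100 * x$at_content))
  cat("Haplotypes:", x$n_haplotypes, "\n")
  invisible(x)
}

#' Shortest contiguous species-diagnostic window
#'
#' Finds the shortest contiguous window of alignment columns in which every
#' pair of sequences from different species differs at at least one complete
#' column — the minimal segment that can by itself identify every sample to
#' species (such a short diagnostic segment is useful when degraded market
#' material yields only short reads). Windows are scanned in ascending
#' length, left to right; the first satisfying window is returned.
#'
#' @param aln A [build_alignment()] object.
#' @param labels Named character vector mapping id to species (or an
#'   alignment/metadata object accepted by the package).
#' @return A list with `start` (0-based) and `length`, or `NULL` if no
#'   window — including the full alignment — is diagnostic.
#' @export
min_diagnostic_window <- function(aln, labels = NULL) {
  stopifnot(inherits(aln, "barcode_alignment"))
  labels <- species_labels(if (is.null(labels)) aln else labels)
  sp <- unname(labels[aln$ids])
  if (length(unique(sp)) < 2L) stop("need at least 2 species")
  comp <- complete_columns(aln)
  n <- nrow(aln$mat)
  # pair x column logical matrix of informative differences
  pairs <- which(outer(sp, sp, "!=") & upper.tri(diag(n)), arr.ind = TRUE)
  diff_mat <- matrix(FALSE, nrow(pairs), aln$n_sites)
  for (p in seq_len(nrow(pairs)))
    diff_mat[p, ] <- (aln$mat[pairs[p, 1L], ] != aln$mat[pairs[p, 2L], ]) & comp
  if (nrow(diff_mat) == 0L) return(NULL)
  for (len in seq_len(aln$n_sites)) {
    for (start in seq_len(aln$n_sites - len + 1L)) {
      cols <- start:(start + len - 1L)
      if (all(rowSums(diff_mat[, cols, drop = FALSE]) > 0L))
        return(list(start = start - 1L, length = len))
    }
  }
  NULL
}
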