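#' COI barcode primer pair used throughout the package
#'
#' The forward/reverse primer pair amplifying the 477-bp COI barcode region
#' of the studied ruminant and chelonian families.
#'
#' @param forward,reverse Primer sequences, 5'->3'.
#' @param max_mismatch Maximum mismatches tolerated per primer; must be
#'   non-negative and below half the primer length.
#' @return An object of class `primer_pair`.
#' @export
primer_pair <- function(forward = "GCAGGAACAGGCTGAACCGT",
                        reverse = "AATATGTGGTGGGCTCATAC",
                        max_mismatch = 2L) {
  forward <- normalize_seq(forward)
  reverse <- normalize_seq(reverse)
  if (nchar(forward) < 10L || nchar(reverse) < 10L)
    stop("primers must be at least 10 nt long")
  if (max_mismatch < 0L || max_mismatch >= min(nchar(forward), nchar(reverse)) / 2)
    stop("max_mismatch must be >= 0 and < primer length / 2")
  structure(list(forward = forward, reverse = reverse,
                 max_mismatch = as.integer(max_mismatch)),
            class = "primer_pair")
}

#' Reverse-complement a nucleotide string
#'
#' Gaps and `N` are preserved; the string is normalised first.
#'
#' @param seq Nucleotide string.
#' @return The reverse complement.
#' @export
revcomp <- function(seq) {
  chars <- rev(strsplit(normalize_seq(seq), "", fixed = TRUE)[[1L]])
  comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N", "-" = "-")
  paste(comp[chars], collapse = "")
}

#' Locate the best primer binding site on a template
#'
#' Scans every offset of the template for the primer (optionally
#' reverse-complemented first) and returns the hit with the fewest
#' mismatches, ties broken by the smallest position. An `N` in the template
#' counts as a mismatch. Absence of a hit within `max_mismatch` is a
#' `NULL` result, not an error.
#'
#' @param template Nucleotide string.
#' @param primer Primer, 5'->3'.
#' @param max_mismatch Maximum tolerated mismatches.
#' @param orientation `"as-given"` or `"reverse-complement"` (primer is
#'   reverse-complemented before matching).
#' @return `NULL`, or a list with `position` (0-based offset of the match
#'   start on the template) and `mismatches`.
#' @export
locate_primer <- function(template, primer, max_mismatch = 0L,
                          orientation = c("as-given", "reverse-complement")) {
  orientation <- match.arg(orientation)
  template <- normalize_seq(template)
  primer <- normalize_seq(primer)
  if (orientation == "reverse-complement") primer <- revcomp(primer)
  tc <- strsplit(template, "", fixed = TRUE)[[1L]]
  pc <- strsplit(primer, "", fixed = TRUE)[[1L]]
  L <- length(pc)
  if (length(tc) < L) stop("template shorter than primer")
  n_off <- length(tc) - L + 1L
  # mismatch count at each offset; N or gap in template never matches
  mm <- vapply(seq_len(n_off), function(i) {
    win <- tc[i:(i + L - 1L)]
    sum(win != pc | win %in% c("N", "-"))
  }, integer(1))
  best <- which.min(mm)  # earliest position among ties
  if (mm[best] > max_mismatch) return(NULL)
  list(position = best - 1L, mismatches = mm[best])
}

#' Crop a template to the barcode amplicon between two primers
#'
#' In-silico PCR: the forward primer is searched as given and the reverse
#' primer as its reverse complement, first on the template's forward strand,
#' then (if either primer is missing) on the global reverse complement of
#' the template, since database sequences may be deposited in either
#' orientation. The forward hit must lie upstream of the reverse hit.
#'
#' @param template Nucleotide string.
#' @param primers A [primer_pair()].
#' @param include_primers If `FALSE` (default) return the insert between the
#'   forward primer's 3' end and the reverse binding site's 5' end; if
#'   `TRUE`, the full amplicon including both primer sites.
#' @param expected_length Optional integer; if supplied, a cropped sequence
#'   of a different length is an error (strict-length audit mode).
#' @return A list with `seq` (the cropped string), `start`/`end` (0-based
#'   half-open coordinates on the matched strand), `strand` (`"forward"` or
#'   `"reverse-complemented"`), and the per-primer mismatch counts.
#' @export
crop_to_barcode <- function(template, primers = primer_pair(),
                            include_primers = FALSE,
                            expected_length = NULL) {
  stopifnot(inherits(primers, "primer_pair"))
  template <- normalize_seq(template)
  for (strand in c("forward", "reverse-complemented")) {
    tmpl <- if (strand == "forward") template else revcomp(template)
    f <- locate_primer(tmpl, primers$forward, primers$max_mismatch, "as-given")
    r <- locate_primer(tmpl, primers$reverse, primers$max_mismatch,
                       "reverse-complement")
    if (!is.null(f) && !is.null(r)) {
      f_end <- f$position + nchar(primers$forward)   # 3' end of fwd primer
      if (f_end > r$position)
        stop("forward primer found downstream of reverse primer ",
             "(orientation conflict)")
      if (include_primers) {
        start <- f$position
        end <- r$position + nchar(primers$reverse)
      } else {
        start <- f_end
        end <- r$position
      }
      out <- substr(tmpl, start + 1L, end)
      if (!is.null(expected_length) && nchar(out) != expected_length)
        stop("cropped length ", nchar(out), " != expected ", expected_length)
      return(list(seq = out, start = start, end = end, strand = strand,
                  mismatches_forward = f$mismatches,
                  mismatches_reverse = r$mismatches))
    }
    if (strand == "forward" && (is.null(f) || is.null(r))) next
  }
  missing <- c(if (is.null(f)) "forward", if (is.null(r)) "reverse")
  stop(paste(missing, collapse = " and "), " primer not found")
}

#' Crop every sequence of a record set to the barcode region
#'
#' @inheritParams crop_to_barcode
#' @param records Data frame with columns `id`, `seq`.
#' @return `records` with `seq` replaced by the cropped sequences.
#' @export
crop_records <- function(records, primers = primer_pair(),
                         include_primers = FALSE, expected_length = NULL) {
  records$seq <- vapply(seq_len(nrow(records)), function(i) {
    res <- tryCatch(
      crop_to_barcode(records$seq[i], primers, include_primers,
                      expected_length),
      error = function(e) stop("record '", records$id[i], "': ",
                               conditionMessage(e), call. = FALSE))
    res$seq
  }, character(1))
  records
}
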