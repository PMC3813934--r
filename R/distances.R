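#' Transition/transversion site counts for a sequence pair
#'
#' Counts sites where both sequences carry an unambiguous base (`A`, `C`,
#' `G`, `T`), and among those the transitions (A<->G, C<->T) and
#' transversions.
#'
#' @param a,b Equal-length nucleotide strings or character vectors.
#' @return A list with `n_scored`, `n_transition`, `n_transversion`.
#' @export
site_pair_counts <- function(a, b) {
  ac <- if (length(a) > 1L) a else strsplit(a, "", fixed = TRUE)[[1L]]
  bc <- if (length(b) > 1L) b else strsplit(b, "", fixed = TRUE)[[1L]]
  if (length(ac) != length(bc)) stop("sequences have unequal lengths")
  ok <- ac %in% c("A", "C", "G", "T") & bc %in% c("A", "C", "G", "T")
  ac <- ac[ok]; bc <- bc[ok]
  diff <- ac != bc
  purine <- c("A", "G")
  ts <- diff & ((ac %in% purine) == (bc %in% purine))
  list(n_scored = sum(ok), n_transition = sum(ts),
       n_transversion = sum(diff & !ts))
}

#' Kimura two-parameter distance between two sequences
#'
#' Kimura's (1980) closed form: with `S` and `V` the transition and
#' transversion fractions over scored sites,
#' \deqn{d = -\tfrac{1}{2}\,\ln\big[(1-2S-V)\sqrt{1-2V}\big].}
#' Sites where either sequence has a gap or `N` are excluded from scoring.
#' Saturation — `1-2S-V <= 0` or `1-2V <= 0`, where the logarithm's domain
#' is exceeded — is an error: an authentication audit must not silently
#' drop evidence.
#'
#' @param a,b Equal-length nucleotide strings or character vectors.
#' @param policy Deletion policy. For a single pair, `"pairwise-deletion"`
#'   and `"complete-deletion-mask"` coincide (both drop sites unscoreable in
#'   either member); the distinction matters at the matrix level, see
#'   [pairwise_matrix()].
#' @return K2P distance in substitutions/site.
#' @export
k2p_distance <- function(a, b,
                         policy = c("pairwise-deletion",
                                    "complete-deletion-mask")) {
  policy <- match.arg(policy)
  cnt <- site_pair_counts(a, b)
  if (cnt$n_scored == 0L) stop("no scoreable sites for this pair")
  k2p_from_fractions(cnt$n_transition / cnt$n_scored,
                     cnt$n_transversion / cnt$n_scored)
}

# closed form on (S, V); shared by distance and tests of limits
k2p_from_fractions <- function(S, V) {
  w1 <- 1 - 2 * S - V
  w2 <- 1 - 2 * V
  if (w1 <= 0 || w2 <= 0)
    stop("saturated pair: K2P distance undefined (S=", signif(S, 4),
         ", V=", signif(V, 4), ")")
  -0.5 * log(w1 * sqrt(w2))
}

#' Pairwise K2P distance matrix
#'
#' @param aln A [build_alignment()] object.
#' @param policy `"pairwise-deletion"` (default; each pair scored over its
#'   own shared unambiguous sites) or `"complete-deletion-mask"` (the whole
#'   alignment is first restricted to columns complete in every sequence).
#' @param on_saturation `"error"` (default) or `"na"` to record `NA` for a
#'   saturated pair and let downstream steps drop it explicitly.
#' @return An object of class `k2p_matrix`: symmetric numeric matrix with
#'   ids as dimnames, in alignment order.
#' @export
pairwise_matrix <- function(aln,
                            policy = c("pairwise-deletion",
                                       "complete-deletion-mask"),
                            on_saturation = c("error", "na")) {
  stopifnot(inherits(aln, "barcode_alignment"))
  policy <- match.arg(policy)
  on_saturation <- match.arg(on_saturation)
  m <- aln$mat
  if (policy == "complete-deletion-mask")
    m <- m[, complete_columns(aln), drop = FALSE]
  n <- nrow(m)
  d <- matrix(0, n, n, dimnames = list(aln$ids, aln$ids))
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      dij <- tryCatch(k2p_distance(m[i, ], m[j, ]), error = function(e) {
        if (on_saturation == "na") NA_real_
        else stop("pair (", aln$ids[i], ", ", aln$ids[j], "): ",
                  conditionMessage(e), call. = FALSE)
      })
      d[i, j] <- d[j, i] <- dij
    }
  }
  structure(d, class = c("k2p_matrix", "matrix", "array"), policy = policy)
}

#' Write a distance matrix as square CSV
#'
#' @param dm A [pairwise_matrix()] result.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_distance_csv <- function(dm, path) {
  utils::write.csv(as.data.frame(unclass(dm)), path, row.names = TRUE)
  invisible(path)
}

#' Write a distance matrix in square PHYLIP format
#'
#' @param dm A [pairwise_matrix()] result.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_distance_phylip <- function(dm, path) {
  ids <- rownames(dm)
  lines <- c(sprintf("%5d", length(ids)),
             vapply(seq_along(ids), function(i)
               paste0(formatC(ids[i], width = -10),
                      paste(sprintf("%.6f", dm[i, ]), collapse = "  ")),
               character(1)))
  writeLines(lines, path)
  invisible(path)
}
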