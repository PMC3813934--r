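#' Neighbor-joining tree from a distance matrix
#'
#' Saitou-Nei agglomeration on the pairwise K2P matrix, producing an
#' unrooted tree (an `ape` `phylo` object). Negative branch lengths, which
#' can arise on non-additive data, are kept as computed by default so that
#' path lengths remain faithful to the agglomeration; set
#' `clamp_negative = TRUE` to zero them.
#'
#' @param dm A [pairwise_matrix()] result (or any symmetric numeric matrix
#'   with id dimnames).
#' @param clamp_negative Zero out negative branch lengths (default `FALSE`).
#' @return An object of class `phylo`.
#' @export
nj_tree <- function(dm, clamp_negative = FALSE) {
  if (nrow(dm) < 3L) stop("neighbor-joining needs at least 3 taxa")
  if (anyNA(dm)) stop("distance matrix contains NA entries")
  if (any(!is.finite(dm))) stop("distance matrix contains non-finite entries")
  tree <- ape::nj(unclass(dm))
  if (clamp_negative) {
    n_neg <- sum(tree$edge.length < 0)
    if (n_neg > 0L) {
      warning(n_neg, " negative branch length(s) clamped to 0")
      tree$edge.length[tree$edge.length < 0] <- 0
    }
  }
  tree
}

# canonical key of the bipartition {side, complement} — root-invariant
bipart_key <- function(side, tips) {
  a <- paste(sort(side), collapse = ",")
  b <- paste(sort(setdiff(tips, side)), collapse = ",")
  if (a < b) paste(a, b, sep = " | ") else paste(b, a, sep = " | ")
}

#' Bipartitions of an unrooted tree
#'
#' Each edge of an unrooted tree splits the leaves in two; the canonical
#' string keys of these splits are the rooting-invariant currency used for
#' bootstrap support and monophyly testing.
#'
#' @param tree A `phylo` object.
#' @param include_trivial Include the leaf edges (singleton splits)?
#' @return Character vector of canonical bipartition keys.
#' @export
tree_bipartitions <- function(tree, include_trivial = FALSE) {
  tips <- tree$tip.label
  pp <- ape::prop.part(tree)
  sets <- lapply(pp, function(idx) tips[idx])
  sets <- Filter(function(s) length(s) < length(tips), sets)  # drop root set
  if (include_trivial) sets <- c(sets, as.list(tips))
  unique(vapply(sets, bipart_key, character(1), tips = tips))
}

#' Bootstrap support for the NJ tree
#'
#' Alignment columns are resampled with replacement `n_replicates` times
#' (seeded); a K2P + NJ tree is rebuilt per replicate, and the support of
#' each internal edge of the original tree is the fraction of successful
#' replicates containing that bipartition. A replicate whose resampled
#' matrix contains a saturated pair is skipped with a warning and reported
#' in `n_skipped` (it does not enter the support denominator).
#'
#' @param aln A [build_alignment()] object.
#' @param n_replicates Number of bootstrap replicates (default 1000).
#' @param seed Integer seed for the column resampling.
#' @param policy Deletion policy passed to [pairwise_matrix()].
#' @return A list with `tree` (the original NJ tree with supports as
#'   internal node labels), `support` (named vector, bipartition key ->
#'   fraction), `n_replicates`, `n_skipped`.
#' @export
bootstrap_support <- function(aln, n_replicates = 1000L, seed = 1L,
                              policy = "pairwise-deletion") {
  stopifnot(inherits(aln, "barcode_alignment"), n_replicates >= 1L)
  dm <- pairwise_matrix(aln, policy)
  tree <- nj_tree(dm)
  target <- tree_bipartitions(tree, include_trivial = FALSE)
  counts <- stats::setNames(numeric(length(target)), target)
  set.seed(seed)
  n_ok <- 0L
  for (b in seq_len(n_replicates)) {
    cols <- sample.int(aln$n_sites, aln$n_sites, replace = TRUE)
    rep_aln <- aln
    rep_aln$mat <- aln$mat[, cols, drop = FALSE]
    rep_aln$n_sites <- length(cols)
    rep_tree <- tryCatch(nj_tree(pairwise_matrix(rep_aln, policy)),
                         error = function(e) NULL)
    if (is.null(rep_tree)) {
      warning("bootstrap replicate ", b, " skipped (saturated distance)")
      next
    }
    n_ok <- n_ok + 1L
    hit <- target %in% tree_bipartitions(rep_tree)
    counts[hit] <- counts[hit] + 1
  }
  support <- if (n_ok > 0L) counts / n_ok else counts * NA_real_
  # attach supports as internal node labels (root label empty)
  tips <- tree$tip.label
  pp <- ape::prop.part(tree)
  keys <- vapply(pp, function(idx) bipart_key(tips[idx], tips), character(1))
  tree$node.label <- ifelse(keys %in% names(support),
                            sprintf("%.3f", support[keys]), "")
  list(tree = tree, support = support,
       n_replicates = n_replicates, n_skipped = n_replicates - n_ok)
}

#' Serialise a tree to Newick
#'
#' Branch lengths are written with 6 decimal places; internal node labels
#' (bootstrap supports, if attached) are preserved. Leaf labels containing
#' Newick metacharacters are an error.
#'
#' @param tree A `phylo` object.
#' @return A single Newick string (terminated by `;`).
#' @export
to_newick <- function(tree) {
  bad <- grepl("[][,;:()' ]", tree$tip.label)
  if (any(bad))
    stop("leaf label(s) contain Newick metacharacters: ",
         paste(tree$tip.label[bad], collapse = ", "))
  tree$edge.length <- round(tree$edge.length, 6L)
  ape::write.tree(tree)
}

#' Read a Newick string or file
#'
#' @param x A Newick string (containing `(`) or a file path.
#' @return A `phylo` object.
#' @export
from_newick <- function(x) {
  if (grepl("(", x, fixed = TRUE)) ape::read.tree(text = x)
  else ape::read.tree(x)
}

#' Per-species monophyly on an unrooted tree
#'
#' A species is monophyletic iff some edge of the unrooted tree separates
#' exactly its leaves from all others; singleton species are trivially
#' monophyletic.
#'
#' @param tree A `phylo` object whose tip labels are sample ids.
#' @param labels id -> species labels.
#' @return Named logical vector, one entry per species.
#' @export
species_monophyly <- function(tree, labels) {
  labels <- species_labels(labels)
  tips <- tree$tip.label
  if (!all(tips %in% names(labels)))
    stop("unlabelled tip(s): ",
         paste(setdiff(tips, names(labels)), collapse = ", "))
  keys <- tree_bipartitions(tree, include_trivial = TRUE)
  sp <- unname(labels[tips])
  out <- vapply(unique(sp), function(s) {
    members <- tips[sp == s]
    if (length(members) == 1L || length(members) == length(tips)) return(TRUE)
    bipart_key(members, tips) %in% keys
  }, logical(1))
  stats::setNames(out, unique(sp))
}
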