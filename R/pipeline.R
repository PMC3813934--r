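#' Run the full barcode trade-monitoring audit
#'
#' One call orchestrating the whole monitoring arm: optional in-silico PCR
#' cropping, alignment construction, alignment summary statistics, K2P
#' distance matrix, intra/interspecific divergence partitioning,
#' barcoding-gap test, leave-one-out identification, neighbor-joining tree
#' with bootstrap support, and per-species monophyly.
#'
#' @param records Data frame with columns `id`, `seq` (and optionally
#'   `species`, `family`, `status`), e.g. from [read_fasta()]; or a path to
#'   a FASTA file.
#' @param metadata Data frame from [read_metadata()] or a TSV path; may be
#'   omitted if `records` already carries a `species` column.
#' @param primers A [primer_pair()] to crop with, or `NULL` (default) if
#'   the sequences are already cropped to the barcode region.
#' @param policy Deletion policy for [pairwise_matrix()].
#' @param threshold Identification threshold (default 0.02, the empirical
#'   boundary between intra- and interspecific divergence).
#' @param n_bootstrap Bootstrap replicates for the NJ tree (0 disables).
#' @param seed Seed for the bootstrap resampling.
#' @return An object of class `barcode_audit` with components
#'   `alignment`, `summary_stats`, `distances`, `divergence`, `gap`,
#'   `identification`, `tree`, `bootstrap`, `monophyly`, `newick`, and a
#'   `config` echo. Supports `print`, `summary`, `plot`.
#' @examples
#' sim <- simulate_barcode_set(barcode_sim_config(n_species = 4,
#'   samples_per_species = 3, seq_length = 300, seed = 7))
#' aud <- barcode_audit(sim$records, n_bootstrap = 0)
#' aud
#' @export
barcode_audit <- function(records, metadata = NULL, primers = NULL,
                          policy = "pairwise-deletion", threshold = 0.02,
                          n_bootstrap = 100L, seed = 1L) {
  if (is.character(records) && length(records) == 1L)
    records <- read_fasta(records)
  if (is.character(metadata) && length(metadata) == 1L)
    metadata <- read_metadata(metadata)
  if (!is.null(metadata)) records <- join_metadata(records, metadata)
  if (!"species" %in% names(records))
    stop("no species labels: supply metadata")
  if (!is.null(primers)) records <- crop_records(records, primers)
  aln <- build_alignment(records)
  labels <- species_labels(aln)
  stats_ <- alignment_summary(aln)
  dm <- pairwise_matrix(aln, policy)
  div <- partition_divergence(dm, labels)
  gap <- barcoding_gap(div)
  loo <- loo_identification(aln, labels, threshold, dm = dm)
  tree <- nj_tree(dm)
  boot <- NULL
  if (n_bootstrap > 0L) {
    boot <- bootstrap_support(aln, n_bootstrap, seed, policy)
    tree <- boot$tree
  }
  mono <- species_monophyly(tree, labels)
  structure(list(
    alignment = aln, summary_stats = stats_, distances = dm,
    divergence = div, gap = gap, identification = loo, tree = tree,
    bootstrap = boot, monophyly = mono, newick = to_newick(tree),
    config = list(policy = policy, threshold = threshold,
                  n_bootstrap = as.integer(n_bootstrap),
                  seed = as.integer(seed),
                  cropped = !is.null(primers))),
    class = "barcode_audit")
}

#' @export
print.barcode_audit <- function(x, ...) {
  cat("Barcode trade-monitoring audit\n")
  cat("==============================\n")
  print(x$alignment)
  print(x$summary_stats)
  print(x$divergence)
  cat(sprintf("Leave-one-out identification: %.1f%% correct (%d eligible, %d singleton quer%s excluded)\n",
              100 * x$identification$success_rate,
              x$identification$n_eligible,
              x$identification$n_excluded_singletons,
              if (x$identification$n_excluded_singletons == 1L) "y" else "ies"))
  cat(sprintf("Species monophyletic on NJ tree: %d / %d\n",
              sum(x$monophyly), length(x$monophyly)))
  invisible(x)
}

#' @export
summary.barcode_audit <- function(object, ...) {
  print(object)
  cat("\nPer-species diagnostics:\n")
  print(object$divergence$per_species, row.names = FALSE)
  invisible(object)
}

#' Histogram of intra- vs interspecific divergences
#'
#' Visualises the barcoding gap: within-species distances near zero,
#' between-species distances far to the right, with (ideally) clear water
#' between the two.
#'
#' @param x A [barcode_audit()] object.
#' @param breaks Passed to [graphics::hist()].
#' @param ... Further plot arguments.
#' @export
plot.barcode_audit <- function(x, breaks = 30, ...) {
  all_d <- c(x$divergence$intra_values, x$divergence$inter_values)
  h <- graphics::hist(all_d, breaks = breaks, plot = FALSE)
  hi <- graphics::hist(x$divergence$intra_values, breaks = h$breaks,
                       plot = FALSE)
  he <- graphics::hist(x$divergence$inter_values, breaks = h$breaks,
                       plot = FALSE)
  graphics::plot(h$mids, hi$counts, type = "h", lwd = 6, col = "steelblue",
                 xlab = "K2P distance (substitutions/site)",
                 ylab = "pairs",
                 main = "Intra- vs interspecific divergence",
                 ylim = c(0, max(hi$counts, he$counts)), ...)
  graphics::points(h$mids, he$counts, type = "h", lwd = 6, col = "tomato")
  graphics::legend("top", fill = c("steelblue", "tomato"),
                   legend = c("intraspecific", "interspecific"), bty = "n")
  invisible(x)
}

# round all numerics to 9 significant digits, recursively (stable reports)
round_sig <- function(x, digits = 9L) {
  if (is.list(x)) lapply(x, round_sig, digits = digits)
  else if (is.double(x)) signif(x, digits)
  else x
}

#' Write a JSON audit report
#'
#' A self-contained report: configuration echo (so every number is
#' reproducible from inputs plus the echo), alignment summary, divergence
#' partition, gap verdicts, identification table and the Newick tree.
#' Numerics are serialised at 9 significant digits for byte-stable output.
#'
#' @param audit A [barcode_audit()] object.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_audit_report <- function(audit, path) {
  stopifnot(inherits(audit, "barcode_audit"))
  div <- audit$divergence
  report <- list(
    config = audit$config,
    alignment_summary = unclass(audit$summary_stats),
    divergence = list(
      mean_intra = div$mean_intra, mean_inter = div$mean_inter,
      max_intra_overall = div$max_intra_overall,
      min_inter_overall = div$min_inter_overall,
      n_intra_pairs = length(div$intra_values),
      n_inter_pairs = length(div$inter_values),
      per_species = div$per_species),
    barcoding_gap = list(global_gap = audit$gap$global_gap,
                         per_species = as.list(audit$gap$per_species)),
    identification = list(
      success_rate = audit$identification$success_rate,
      n_eligible = audit$identification$n_eligible,
      n_excluded_singletons = audit$identification$n_excluded_singletons,
      results = audit$identification$results),
    monophyly = as.list(audit$monophyly),
    newick = audit$newick,
    tool = list(package = "adtrace",
                version = as.character(utils::packageVersion("adtrace"))))
  jsonlite::write_json(round_sig(report), path, auto_unbox = TRUE,
                       digits = NA, na = "null", pretty = TRUE)
  invisible(path)
}
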