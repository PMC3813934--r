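# tie tolerance for "equally close" references (machine-precision ties)
.TIE_EPS <- 1e-12

#' Partition pairwise divergences into intra- and interspecific sets
#'
#' Every unordered pair of samples is classified as intraspecific (same
#' species) or interspecific; means, extrema and per-species gap
#' diagnostics are computed. For a singleton species the maximal
#' intraspecific distance is undefined: it is reported as `NA`, excluded
#' from the overall maximum, and its gap flag is assessed against 0 and
#' flagged as a singleton.
#'
#' @param dm A [pairwise_matrix()] result.
#' @param labels Named character vector id -> species (or an object accepted
#'   by the package's label helpers).
#' @return An object of class `divergence_summary`: intra/inter value
#'   vectors, their means and extrema, and a per-species data frame with
#'   `max_intra`, `min_inter` (distance to the nearest non-conspecific) and
#'   `gap_present`.
#' @export
partition_divergence <- function(dm, labels) {
  labels <- species_labels(labels)
  ids <- rownames(dm)
  if (!all(ids %in% names(labels)))
    stop("unlabelled id(s): ",
         paste(setdiff(ids, names(labels)), collapse = ", "))
  sp <- unname(labels[ids])
  if (length(unique(sp)) < 2L)
    stop("only one species present: interspecific set is empty")
  if (anyNA(dm)) stop("distance matrix contains NA (saturated pairs?)")
  n <- length(ids)
  same <- outer(sp, sp, "==")
  ut <- upper.tri(dm)
  intra <- dm[ut & same]
  inter <- dm[ut & !same]
  per_sp <- do.call(rbind, lapply(unique(sp), function(s) {
    in_s <- sp == s
    intra_s <- dm[in_s, in_s, drop = FALSE][upper.tri(diag(sum(in_s)))]
    max_intra <- if (length(intra_s)) max(intra_s) else NA_real_
    min_inter <- min(dm[in_s, !in_s, drop = FALSE])
    data.frame(species = s, n_samples = sum(in_s),
               max_intra = max_intra, min_inter = min_inter,
               singleton = sum(in_s) == 1L,
               gap_present = min_inter >
                 (if (is.na(max_intra)) 0 else max_intra))
  }))
  rownames(per_sp) <- NULL
  structure(list(
    intra_values = intra, inter_values = inter,
    mean_intra = mean(intra), mean_inter = mean(inter),
    max_intra_overall = if (length(intra)) max(intra) else NA_real_,
    min_inter_overall = min(inter),
    per_species = per_sp), class = "divergence_summary")
}

#' @export
print.divergence_summary <- function(x, ...) {
  cat(sprintf("Intraspecific: n=%d, mean=%.2f%%, max=%s\n",
              length(x$intra_values), 100 * x$mean_intra,
              if (is.na(x$max_intra_overall)) "NA"
              else sprintf("%.2f%%", 100 * x$max_intra_overall)))
  cat(sprintf("Interspecific: n=%d, mean=%.2f%%, min=%.2f%%\n",
              length(x$inter_values), 100 * x$mean_inter,
              100 * x$min_inter_overall))
  gap <- barcoding_gap(x)
  cat("Global barcoding gap:", if (gap$global_gap) "present" else "ABSENT",
      "\n")
  invisible(x)
}

#' Barcoding-gap test
#'
#' The global gap is present iff the largest intraspecific distance is
#' strictly below the smallest interspecific distance; per-species flags
#' come from [partition_divergence()].
#'
#' @param summary A [partition_divergence()] result.
#' @return A list with `global_gap` (logical) and `per_species` flags.
#' @export
barcoding_gap <- function(summary) {
  stopifnot(inherits(summary, "divergence_summary"))
  max_intra <- summary$max_intra_overall
  global <- summary$min_inter_overall >
    (if (is.na(max_intra)) 0 else max_intra)
  list(global_gap = global,
       per_species = stats::setNames(summary$per_species$gap_present,
                                     summary$per_species$species))
}

#' Identify one query by best close match
#'
#' The query is assigned the species of its nearest labelled reference(s),
#' unless that minimal distance exceeds the threshold (`no_id`) or the
#' nearest references (ties within machine precision) span two or more
#' species (`ambiguous`). When the true species is supplied the decision is
#' scored `correct`/`incorrect`.
#'
#' @param query_id Id of the query row in `dm`.
#' @param dm A [pairwise_matrix()] over queries and references together.
#' @param labels Named vector id -> species for the references (the query's
#'   own label, if present, is ignored during matching).
#' @param threshold Maximum distance for a positive identification
#'   (default 0.02, the empirical intra/inter boundary).
#' @param truth Optional true species of the query.
#' @return A list with `query_id`, `assigned_species` (or `NA`),
#'   `best_distance`, and `decision` (`correct`, `incorrect`, `ambiguous`,
#'   `no_id`, or `assigned` when no truth is given).
#' @export
identify <- function(query_id, dm, labels, threshold = 0.02, truth = NULL) {
  labels <- species_labels(labels)
  refs <- setdiff(intersect(rownames(dm), names(labels)), query_id)
  if (length(refs) == 0L) stop("no labelled references")
  d <- dm[query_id, refs]
  if (anyNA(d)) stop("NA distances from query ", query_id)
  best <- min(d)
  if (best > threshold)
    return(list(query_id = query_id, assigned_species = NA_character_,
                best_distance = best, decision = "no_id"))
  tied_sp <- unique(unname(labels[refs[d <= best + .TIE_EPS]]))
  if (length(tied_sp) >= 2L)
    return(list(query_id = query_id, assigned_species = NA_character_,
                best_distance = best, decision = "ambiguous"))
  decision <- if (is.null(truth)) "assigned"
              else if (tied_sp == truth) "correct" else "incorrect"
  list(query_id = query_id, assigned_species = tied_sp,
       best_distance = best, decision = decision)
}

#' Leave-one-out identification success
#'
#' Each sequence in turn is treated as an unknown and identified against all
#' the others. Queries whose species has no other representative cannot be
#' identified correctly by construction; they are excluded from the success
#' denominator and reported separately.
#'
#' @param aln A [build_alignment()] object (or a precomputed
#'   [pairwise_matrix()] via `dm`).
#' @param labels id -> species labels.
#' @param threshold Identification threshold (default 0.02).
#' @param dm Optional precomputed distance matrix (avoids recomputation).
#' @return A list with `success_rate` (correct / eligible), `n_eligible`,
#'   `n_excluded_singletons`, and a per-query results data frame.
#' @export
loo_identification <- function(aln, labels = NULL, threshold = 0.02,
                               dm = NULL) {
  if (is.null(dm)) dm <- pairwise_matrix(aln)
  labels <- species_labels(if (is.null(labels)) aln else labels)
  ids <- rownames(dm)
  sp <- unname(labels[ids])
  counts <- table(sp)
  res <- lapply(seq_along(ids), function(i) {
    r <- identify(ids[i], dm, labels, threshold, truth = sp[i])
    r$eligible <- counts[[sp[i]]] >= 2L
    r
  })
  tab <- data.frame(
    query_id = vapply(res, `[[`, character(1), "query_id"),
    true_species = sp,
    assigned_species = vapply(res, `[[`, character(1), "assigned_species"),
    best_distance = vapply(res, `[[`, numeric(1), "best_distance"),
    decision = vapply(res, `[[`, character(1), "decision"),
    eligible = vapply(res, `[[`, logical(1), "eligible"))
  eligible <- tab[tab$eligible, ]
  list(success_rate = if (nrow(eligible))
         mean(eligible$decision == "correct") else NA_real_,
       n_eligible = nrow(eligible),
       n_excluded_singletons = sum(!tab$eligible),
       results = tab)
}
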