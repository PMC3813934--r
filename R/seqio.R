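#' Read a FASTA file of barcode sequences
#'
#' Reads a (wrapped or unwrapped) multi-record FASTA file and normalises the
#' sequences for downstream barcode analysis: bases are uppercased, `U` is
#' mapped to `T`, and IUPAC ambiguity codes other than `N` are collapsed to
#' `N` (with a warning), because the distance machinery scores only
#' `A`/`C`/`G`/`T`. The record id is the header token before the first
#' whitespace.
#'
#' @param path Path to a FASTA file.
#' @return A data frame with columns `id` and `seq`, one row per record, in
#'   file order.
#' @seealso [write_fasta()], [build_alignment()]
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  recs <- seqinr::read.fasta(path, as.string = TRUE, seqtype = "DNA",
                             forceDNAtolower = FALSE, seqonly = FALSE)
  if (length(recs) == 0L) stop("empty FASTA file: ", path)
  ids <- vapply(recs, function(r) attr(r, "name"), character(1))
  dup <- unique(ids[duplicated(ids)])
  if (length(dup) > 0L)
    stop("duplicate sequence id(s) in FASTA: ", paste(dup, collapse = ", "))
  seqs <- vapply(recs, function(r) normalize_seq(as.character(r)[1L]),
                 character(1))
  data.frame(id = unname(ids), seq = unname(seqs), stringsAsFactors = FALSE)
}

# uppercase, U->T, ambiguity codes (other than N) -> N; validates alphabet
normalize_seq <- function(s) {
  s <- toupper(s)
  s <- gsub("U", "T", s, fixed = TRUE)
  chars <- strsplit(s, "", fixed = TRUE)[[1L]]
  if (length(chars) == 0L) stop("empty sequence")
  ambig <- chars %in% c("R", "Y", "S", "W", "K", "M", "B", "D", "H", "V")
  if (any(ambig)) {
    warning(sum(ambig), " IUPAC ambiguity code(s) collapsed to N")
    chars[ambig] <- "N"
  }
  bad <- setdiff(unique(chars), c("A", "C", "G", "T", "N", "-"))
  if (length(bad) > 0L)
    stop("invalid characters in sequence: ", paste(bad, collapse = ", "))
  paste(chars, collapse = "")
}

#' Write sequences to a FASTA file
#'
#' @param records Data frame with columns `id` and `seq` (as returned by
#'   [read_fasta()]).
#' @param path Output path.
#' @param linewidth Characters per sequence line.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path, linewidth = 60L) {
  stopifnot(is.data.frame(records), all(c("id", "seq") %in% names(records)))
  seqinr::write.fasta(as.list(records$seq), names = records$id,
                      file.out = path, nbchar = linewidth)
  invisible(path)
}

#' Read a sample metadata table
#'
#' Reads a tab-separated metadata table with the exact header columns `id`,
#' `species`, `family`, `status`. Status must be one of `wild`, `domestic`,
#' `market` or `reference`; any other value is an error, because
#' trade-monitoring verdicts must never be computed on mislabelled samples.
#'
#' @param path Path to a TSV file.
#' @return A data frame with columns `id`, `species`, `family`, `status`.
#' @export
read_metadata <- function(path) {
  if (!file.exists(path)) stop("metadata file not found: ", path)
  md <- utils::read.delim(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE, colClasses = "character")
  need <- c("id", "species", "family", "status")
  if (!all(need %in% names(md)))
    stop("metadata must have columns: ", paste(need, collapse = ", "))
  md <- md[, need]
  dup <- unique(md$id[duplicated(md$id)])
  if (length(dup) > 0L)
    stop("duplicate id(s) in metadata: ", paste(dup, collapse = ", "))
  bad <- setdiff(unique(md$status), c("wild", "domestic", "market", "reference"))
  if (length(bad) > 0L)
    stop("invalid status value(s): ", paste(bad, collapse = ", "),
         " (allowed: wild, domestic, market, reference)")
  md
}

#' Join sequence records with their metadata, strictly
#'
#' Every sequence id must appear in the metadata; missing ids are an error
#' (never a silent drop).
#'
#' @param records Data frame with columns `id`, `seq`.
#' @param metadata Data frame as returned by [read_metadata()].
#' @return `records` with `species`, `family`, `status` columns appended.
#' @export
join_metadata <- function(records, metadata) {
  missing <- setdiff(records$id, metadata$id)
  if (length(missing) > 0L)
    stop("id(s) present in sequences but absent from metadata: ",
         paste(missing, collapse = ", "))
  m <- match(records$id, metadata$id)
  cbind(records,
        metadata[m, c("species", "family", "status"), drop = FALSE],
        row.names = NULL)
}

#' Build an alignment from equal-length sequences
#'
#' Sequences from one cropped amplicon share coordinates, so the alignment is
#' just the stacked site matrix; no aligner is run. Unequal lengths are an
#' error naming the offending records.
#'
#' @param records Data frame with columns `id`, `seq` (species/family/status
#'   columns, if present, are carried along).
#' @return An object of class `barcode_alignment`: a list with `ids`, the
#'   character site matrix `mat` (rows = sequences), `n_sites`, and any
#'   metadata columns.
#' @export
build_alignment <- function(records) {
  stopifnot(is.data.frame(records), all(c("id", "seq") %in% names(records)))
  if (nrow(records) < 2L) stop("an alignment needs at least 2 sequences")
  dup <- unique(records$id[duplicated(records$id)])
  if (length(dup) > 0L)
    stop("duplicate sequence id(s): ", paste(dup, collapse = ", "))
  lens <- nchar(records$seq)
  if (length(unique(lens)) != 1L) {
    off <- records$id[lens != lens[1L]]
    stop("sequences have unequal lengths: ",
         paste(paste0(records$id, "=", lens), collapse = ", "),
         " (offending: ", paste(off, collapse = ", "), ")")
  }
  mat <- t(vapply(strsplit(records$seq, "", fixed = TRUE), identity,
                  character(lens[1L])))
  rownames(mat) <- records$id
  meta_cols <- intersect(c("species", "family", "status"), names(records))
  structure(list(ids = records$id, mat = mat, n_sites = ncol(mat),
                 meta = if (length(meta_cols))
                   records[, c("id", meta_cols), drop = FALSE] else NULL),
            class = "barcode_alignment")
}

#' @export
print.barcode_alignment <- function(x, ...) {
  cat("Barcode alignment: ", length(x$ids), " sequences x ", x$n_sites,
      " sites\n", sep = "")
  if (!is.null(x$meta) && "species" %in% names(x$meta))
    cat("Species: ", length(unique(x$meta$species)), "\n", sep = "")
  invisible(x)
}

#' Extract id -> species labels
#'
#' Normalises the various label carriers (a labelled alignment, a metadata
#' or record data frame, or an already-named character vector) into the
#' named vector `id -> species` the audit functions consume.
#'
#' @param x A `barcode_alignment` with metadata, a data frame with `id` and
#'   `species` columns, or a named character vector.
#' @return Named character vector mapping id to species.
#' @export
species_labels <- function(x) {
  if (inherits(x, "barcode_alignment")) {
    if (is.null(x$meta) || !"species" %in% names(x$meta))
      stop("alignment carries no species labels")
    stats::setNames(x$meta$species, x$meta$id)
  } else if (is.data.frame(x)) {
    stats::setNames(x$species, x$id)
  } else x
}
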