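# shared fixture builders: everything is generated in code at test time

MAHF1 <- "GCAGGAACAGGCTGAACCGT"
MAHR1 <- "AATATGTGGTGGGCTCATAC"

# alignment from a named character vector of sequences
make_aln <- function(seqs, species = NULL) {
  df <- data.frame(id = names(seqs), seq = unname(seqs),
                   stringsAsFactors = FALSE)
  if (!is.null(species)) df$species <- unname(species[names(seqs)])
  build_alignment(df)
}

# write a FASTA string to a temp file
tmp_fasta <- function(text) {
  f <- tempfile(fileext = ".fa")
  writeLines(text, f)
  f
}

tmp_tsv <- function(df) {
  f <- tempfile(fileext = ".tsv")
  write.table(df, f, sep = "\t", quote = FALSE, row.names = FALSE)
  f
}

# independent reverse-complement oracle (chartr-based, unlike the package's)
rc_oracle <- function(s) {
  paste(rev(strsplit(chartr("ACGT", "TGCA", s), "")[[1]]), collapse = "")
}

# independent K2P oracle: own counting loop + closed form
k2p_oracle <- function(a, b) {
  ac <- strsplit(a, "")[[1]]; bc <- strsplit(b, "")[[1]]
  ok <- ac %in% c("A","C","G","T") & bc %in% c("A","C","G","T")
  ac <- ac[ok]; bc <- bc[ok]
  n <- length(ac)
  ts <- 0; tv <- 0
  for (i in seq_len(n)) {
    if (ac[i] != bc[i]) {
      pur <- c("A", "G")
      if ((ac[i] %in% pur) == (bc[i] %in% pur)) ts <- ts + 1 else tv <- tv + 1
    }
  }
  S <- ts / n; V <- tv / n
  -0.5 * log((1 - 2 * S - V) * sqrt(1 - 2 * V))
}

# random sequence of length n over ACGT
rand_seq <- function(n) paste(sample(c("A","C","G","T"), n, TRUE), collapse = "")

# mutate a sequence at exactly the given numbers of transitions/transversions
mutate_counts <- function(seq, n_ts, n_tv) {
  chars <- strsplit(seq, "")[[1]]
  pos <- sample(length(chars), n_ts + n_tv)
  ts_map <- c(A = "G", G = "A", C = "T", T = "C")
  tv_map <- c(A = "C", G = "C", C = "A", T = "A")
  for (i in seq_len(n_ts)) chars[pos[i]] <- ts_map[[chars[pos[i]]]]
  for (i in seq_len(n_tv)) {
    p <- pos[n_ts + i]
    chars[p] <- tv_map[[chars[p]]]
  }
  paste(chars, collapse = "")
}

# brute-force diagnostic-window oracle (independent of the package's scan)
window_oracle <- function(mat, sp) {
  n <- nrow(mat); L <- ncol(mat)
  comp <- sapply(seq_len(L), function(j) !any(mat[, j] %in% c("-", "N")))
  for (len in 1:L) for (s in 1:(L - len + 1)) {
    cols <- s:(s + len - 1)
    ok <- TRUE
    for (i in 1:(n - 1)) for (j in (i + 1):n) {
      if (sp[i] != sp[j]) {
        d <- any(mat[i, cols] != mat[j, cols] & comp[cols])
        if (!d) { ok <- FALSE; break }
      }
      if (!ok) break
    }
    if (ok) return(list(start = s - 1, length = len))
  }
  NULL
}

# minimal thermo_params stub with chosen k and P_peak
make_params <- function(k, P_peak, id = "x", group = "control") {
  structure(list(sample_id = id, group = group, k = k, P0 = 1,
                 fit_r2 = 1, P_peak = P_peak, t_peak = 10, Q_total = 100),
            class = "thermo_params")
}
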