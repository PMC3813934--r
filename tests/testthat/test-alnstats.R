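test_that("classify_sites counts complete and polymorphic columns", {
  aln <- make_aln(c(a = "AAT", b = "AAT", c = "AAC"))
  expect_equal(classify_sites(aln),
               list(n_sites = 3, n_complete = 3, n_polymorphic = 1))

  # gapped columns are excluded from polymorphism counting entirely
  aln2 <- make_aln(c(a = "A-", b = "AA"))
  expect_equal(classify_sites(aln2),
               list(n_sites = 2, n_complete = 1, n_polymorphic = 0))

  # N behaves like a gap for completeness
  aln3 <- make_aln(c(a = "ANT", b = "AGT", c = "AGC"))
  expect_equal(classify_sites(aln3)$n_complete, 2)
})

test_that("nucleotide diversity matches hand-enumerated pair averages", {
  a <- paste(rep("A", 10), collapse = "")
  b <- paste(c(rep("A", 9), "T"), collapse = "")
  expect_equal(nucleotide_diversity(make_aln(c(x = a, y = b))), 0.1)

  same <- make_aln(c(x = a, y = a, z = a))
  expect_equal(nucleotide_diversity(same), 0)

  # 3 seqs, pairwise diffs 1, 2, 1 over 4 sites -> (4/3)/4
  tri <- make_aln(c(x = "AAAA", y = "AAAT", z = "AATT"))
  expect_equal(nucleotide_diversity(tri), (4 / 3) / 4)

  allgap <- make_aln(c(x = "--", y = "AA"))
  expect_error(nucleotide_diversity(allgap), "no complete columns")
})

test_that("base composition averages per-sequence frequencies", {
  one <- make_aln(c(x = "ACGTACGT", y = "ACGTACGT"))
  bc <- base_composition(one)
  expect_equal(unlist(bc[c("freq_T", "freq_C", "freq_A", "freq_G")]),
               c(freq_T = 0.25, freq_C = 0.25, freq_A = 0.25, freq_G = 0.25))
  expect_equal(bc$at_content, 0.5)

  two <- make_aln(c(x = "AAAA", y = "TTTT"))
  bc2 <- base_composition(two)
  expect_equal(bc2$freq_A, 0.5)
  expect_equal(bc2$freq_T, 0.5)
  expect_equal(bc2$at_content, 1.0)

  # gaps/N excluded from the per-sequence denominator
  gapped <- make_aln(c(x = "AA--", y = "AATT"))
  expect_equal(base_composition(gapped)$freq_A, mean(c(1, 0.5)))

  expect_error(base_composition(make_aln(c(x = "NN--", y = "ACGT"))), "x")
})

test_that("haplotype counting deduplicates over complete columns", {
  expect_equal(count_haplotypes(make_aln(c(a = "AAT", b = "AAT", c = "AAT"))), 1)
  expect_equal(count_haplotypes(make_aln(c(a = "AAT", b = "AAC", c = "AAT"))), 2)
  # projection onto complete columns merges seqs differing only at gapped sites
  expect_equal(count_haplotypes(make_aln(c(a = "A-", b = "AA"))), 1)
})

test_that("statistics are invariant under record reordering", {
  set.seed(11)
  seqs <- setNames(replicate(6, rand_seq(40)), paste0("s", 1:6))
  aln <- make_aln(seqs)
  perm <- make_aln(seqs[c(4, 2, 6, 1, 5, 3)])
  expect_equal(classify_sites(aln), classify_sites(perm))
  expect_equal(nucleotide_diversity(aln), nucleotide_diversity(perm))
  expect_equal(base_composition(aln), base_composition(perm))
  expect_equal(count_haplotypes(aln), count_haplotypes(perm))
})

test_that("pi on simulated pairs converges to the generating divergence", {
  # 50 replicate pairs at low divergence (negligible multiple hits)
  set.seed(101)
  d <- 0.01
  pis <- replicate(50, {
    anc <- rand_seq(2000)
    aln <- make_aln(c(a = evolve_sequence(anc, d / 2, 4),
                      b = evolve_sequence(anc, d / 2, 4)))
    nucleotide_diversity(aln)
  })
  se <- sd(pis) / sqrt(length(pis))
  expect_lt(abs(mean(pis) - d), 3 * se + 1e-4)
})

test_that("min_diagnostic_window finds the shortest diagnostic segment", {
  sp <- c(a = "sp1", b = "sp2", c = "sp3")
  aln <- make_aln(c(a = "AAAA", b = "AATA", c = "AACA"), species = sp)
  expect_equal(min_diagnostic_window(aln), list(start = 2, length = 1))

  # identical sequences from different species: impossible
  same <- make_aln(c(a = "AAAA", b = "AAAA"),
                   species = c(a = "sp1", b = "sp2"))
  expect_null(min_diagnostic_window(same))

  expect_error(min_diagnostic_window(
    make_aln(c(a = "AT", b = "AA"), species = c(a = "sp1", b = "sp1"))),
    "2 species")
})

test_that("diagnostic window matches a brute-force oracle on small alignments", {
  set.seed(23)
  for (rep in 1:20) {
    n <- sample(3:5, 1)
    L <- sample(5:12, 1)
    mat <- matrix(sample(c("A", "C", "G", "T", "-"), n * L, TRUE,
                         prob = c(rep(0.23, 4), 0.08)), n, L)
    ids <- paste0("s", 1:n)
    sp <- setNames(sample(c("x", "y"), n, TRUE), ids)
    if (length(unique(sp)) < 2) sp[1] <- setdiff(c("x", "y"), sp[1])
    rownames(mat) <- ids
    aln <- structure(list(ids = ids, mat = mat, n_sites = L, meta = NULL),
                     class = "barcode_alignment")
    got <- min_diagnostic_window(aln, sp)
    want <- window_oracle(mat, unname(sp[ids]))
    expect_equal(got, want, info = paste("rep", rep))
  }
})
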