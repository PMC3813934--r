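# distance matrix from explicit entries
make_dm <- function(ids, fill) {
  d <- matrix(0, length(ids), length(ids), dimnames = list(ids, ids))
  for (k in seq_len(nrow(fill))) {
    i <- fill$i[k]; j <- fill$j[k]
    d[i, j] <- d[j, i] <- fill$d[k]
  }
  structure(d, class = c("k2p_matrix", "matrix", "array"))
}

test_that("divergence partitioning averages intra and inter pairs", {
  ids <- c("a1", "a2", "b1", "b2")
  labels <- c(a1 = "spA", a2 = "spA", b1 = "spB", b2 = "spB")
  fill <- expand.grid(i = ids, j = ids, stringsAsFactors = FALSE)
  fill <- fill[fill$i < fill$j, ]
  fill$d <- ifelse(substr(fill$i, 1, 1) == substr(fill$j, 1, 1), 0.01, 0.20)
  dm <- make_dm(ids, fill)
  div <- partition_divergence(dm, labels)
  expect_equal(length(div$intra_values), 2)
  expect_equal(length(div$inter_values), 4)
  expect_equal(div$mean_intra, 0.01)
  expect_equal(div$mean_inter, 0.20)
  expect_true(barcoding_gap(div)$global_gap)
  expect_true(all(div$per_species$gap_present))

  expect_error(partition_divergence(dm, setNames(rep("spA", 4), ids)),
               "one species")
})

test_that("partition sizes always sum to n(n-1)/2", {
  set.seed(71)
  for (rep in 1:20) {
    n <- sample(4:12, 1)
    ids <- paste0("s", seq_len(n))
    d <- matrix(runif(n * n, 0.01, 0.3), n, n, dimnames = list(ids, ids))
    d <- (d + t(d)) / 2; diag(d) <- 0
    labels <- setNames(sample(c("u", "v", "w"), n, TRUE), ids)
    if (length(unique(labels)) < 2) labels[1] <- "zzz"
    div <- partition_divergence(
      structure(d, class = c("k2p_matrix", "matrix", "array")), labels)
    expect_equal(length(div$intra_values) + length(div$inter_values),
                 n * (n - 1) / 2)
  }
})

test_that("barcoding gap verdict follows max-intra vs min-inter", {
  ids <- c("a1", "a2", "b1", "b2")
  labels <- c(a1 = "A", a2 = "A", b1 = "B", b2 = "B")
  near <- make_dm(ids, data.frame(
    i = c("a1", "a1", "a1", "a2", "a2", "b1"),
    j = c("a2", "b1", "b2", "b1", "b2", "b2"),
    d = c(0.018, 0.020, 0.021, 0.022, 0.020, 0.015)))
  div <- partition_divergence(near, labels)
  expect_equal(div$max_intra_overall, 0.018)
  expect_equal(div$min_inter_overall, 0.020)
  expect_true(barcoding_gap(div)$global_gap)

  # overlap destroys the gap: push one inter pair below max intra
  overlap <- near
  overlap["a1", "b1"] <- overlap["b1", "a1"] <- 0.010
  expect_false(barcoding_gap(partition_divergence(overlap, labels))$global_gap)
})

test_that("singleton species are flagged and excluded from max-intra", {
  ids <- c("a1", "a2", "c1")
  labels <- c(a1 = "A", a2 = "A", c1 = "C")
  dm <- make_dm(ids, data.frame(i = c("a1", "a1", "a2"),
                                j = c("a2", "c1", "c1"),
                                d = c(0.01, 0.15, 0.16)))
  div <- partition_divergence(dm, labels)
  per <- div$per_species
  expect_true(per$singleton[per$species == "C"])
  expect_true(is.na(per$max_intra[per$species == "C"]))
  expect_equal(per$min_inter[per$species == "C"], 0.15)
  expect_equal(div$max_intra_overall, 0.01)
  # the singleton contributes only inter pairs: 1 intra + 2 inter = 3 pairs
  expect_equal(length(div$intra_values), 1)
  expect_equal(length(div$inter_values), 2)
})

test_that("best-close-match identification handles hits, ties and no-id", {
  ids <- c("q", "r1", "r2", "r3")
  labels <- c(r1 = "A", r2 = "B", r3 = "B")
  dm <- make_dm(ids, data.frame(i = c("q", "q", "q"),
                                j = c("r1", "r2", "r3"),
                                d = c(0.001, 0.05, 0.06)))
  res <- identify("q", dm, labels, threshold = 0.02)
  expect_equal(res$assigned_species, "A")
  expect_equal(res$decision, "assigned")
  expect_equal(identify("q", dm, labels, 0.02, truth = "A")$decision,
               "correct")

  tie <- make_dm(ids, data.frame(i = c("q", "q", "q"),
                                 j = c("r1", "r2", "r3"),
                                 d = c(0.01, 0.01, 0.06)))
  expect_equal(identify("q", tie, labels, 0.02)$decision, "ambiguous")

  far <- make_dm(ids, data.frame(i = c("q", "q", "q"),
                                 j = c("r1", "r2", "r3"),
                                 d = c(0.10, 0.15, 0.16)))
  res_far <- identify("q", far, labels, 0.02)
  expect_equal(res_far$decision, "no_id")
  expect_true(is.na(res_far$assigned_species))
})

test_that("leave-one-out succeeds fully on well-separated simulations", {
  for (seed in 1:5) {
    sim <- simulate_barcode_set(barcode_sim_config(
      n_species = 5, samples_per_species = 5, seq_length = 300, seed = seed))
    loo <- loo_identification(build_alignment(sim$records))
    expect_equal(loo$success_rate, 1.0, info = paste("seed", seed))
    expect_equal(loo$n_eligible, 25)
  }
})

test_that("identical cross-species sequences cannot be identified", {
  s <- strrep("ACGT", 20)
  aln <- make_aln(c(x1 = s, x2 = s, y1 = s, y2 = s))
  labels <- c(x1 = "X", x2 = "X", y1 = "Y", y2 = "Y")
  loo <- loo_identification(aln, labels)
  expect_equal(loo$success_rate, 0)
  expect_true(all(loo$results$decision == "ambiguous"))
})

test_that("singleton-species queries are excluded from the denominator", {
  set.seed(81)
  anc <- rand_seq(200)
  spA <- evolve_sequence(anc, 0.1, 4)
  spB <- evolve_sequence(anc, 0.1, 4)
  aln <- make_aln(c(a1 = evolve_sequence(spA, 0.002, 4),
                    a2 = evolve_sequence(spA, 0.002, 4),
                    b1 = spB))
  labels <- c(a1 = "A", a2 = "A", b1 = "B")
  loo <- loo_identification(aln, labels)
  expect_equal(loo$n_eligible, 2)
  expect_equal(loo$n_excluded_singletons, 1)
  expect_equal(loo$success_rate, 1.0)
})
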