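#' Configuration for simulated barcode datasets
#'
#' Defaults emulate the structure of a market survey of animal-derived
#' medicinal materials: 15 species in 4 families, 72 samples of a 477-bp
#' COI barcode, within-species divergence about 0.4% and between-species
#' divergence about 15.8% (expected substitutions/site).
#'
#' @param n_species Number of species.
#' @param samples_per_species Integer vector (recycled/truncated to
#'   `n_species`) or a single constant; `NULL` distributes `n_total` as
#'   evenly as possible.
#' @param n_total Total sample count used when `samples_per_species` is
#'   `NULL`.
#' @param seq_length Barcode length in bp.
#' @param kappa Transition/transversion rate ratio of the substitution
#'   process.
#' @param inter_divergence Expected between-species substitutions/site.
#' @param intra_divergence Expected within-species substitutions/site.
#' @param n_families Number of family-level clusters (deeper splits).
#' @param seed Integer seed; the generator is a pure function of
#'   (config, seed).
#' @return A list of class `barcode_sim_config`.
#' @export
barcode_sim_config <- function(n_species = 15L, samples_per_species = NULL,
                               n_total = 72L, seq_length = 477L,
                               kappa = 4, inter_divergence = 0.158,
                               intra_divergence = 0.004, n_families = 4L,
                               seed = 1L) {
  if (is.null(samples_per_species)) {
    base <- n_total %/% n_species
    extra <- n_total %% n_species
    samples_per_species <- rep(base, n_species) +
      rep(c(1L, 0L), c(extra, n_species - extra))
  } else if (length(samples_per_species) == 1L) {
    samples_per_species <- rep(as.integer(samples_per_species), n_species)
  }
  stopifnot(length(samples_per_species) == n_species,
            inter_divergence > intra_divergence, intra_divergence >= 0,
            seq_length >= 24L, kappa > 0, n_families >= 1L,
            n_families <= n_species)
  structure(list(n_species = as.integer(n_species),
                 samples_per_species = as.integer(samples_per_species),
                 seq_length = as.integer(seq_length), kappa = kappa,
                 inter_divergence = inter_divergence,
                 intra_divergence = intra_divergence,
                 n_families = as.integer(n_families),
                 seed = as.integer(seed)),
            class = "barcode_sim_config")
}

#' Evolve a sequence under the two-parameter substitution process
#'
#' Forward simulation of the Kimura two-parameter process: per site,
#' substitution events are drawn with exponential waiting times under a
#' rate matrix with transitions at `kappa` times the per-target
#' transversion rate, normalised so the expected number of substitutions
#' per site equals `branch_length`. Multiple hits are allowed, so the
#' multiple-hit correction of the distance estimator is genuinely
#' exercised. Gaps and `N` are left untouched.
#'
#' @param seq Nucleotide string.
#' @param branch_length Expected substitutions/site (>= 0).
#' @param kappa Transition/transversion rate ratio.
#' @return The mutated sequence (string). Uses the current RNG state; seed
#'   with `set.seed()` for reproducibility.
#' @export
evolve_sequence <- function(seq, branch_length, kappa = 4) {
  stopifnot(branch_length >= 0)
  chars <- strsplit(seq, "", fixed = TRUE)[[1L]]
  if (branch_length == 0) return(seq)
  beta <- 1 / (kappa + 2)        # per-target transversion rate
  alpha <- kappa * beta          # transition rate; total rate alpha+2beta = 1
  transition <- c(A = "G", G = "A", C = "T", T = "C")
  transversions <- list(A = c("C", "T"), G = c("C", "T"),
                        C = c("A", "G"), T = c("A", "G"))
  scoreable <- which(chars %in% c("A", "C", "G", "T"))
  for (i in scoreable) {
    t_elapsed <- stats::rexp(1L)
    while (t_elapsed <= branch_length) {
      if (stats::runif(1L) < alpha)  # total rate 1: P(transition) = alpha
        chars[i] <- transition[[chars[i]]]
      else
        chars[i] <- sample(transversions[[chars[i]]], 1L)
      t_elapsed <- t_elapsed + stats::rexp(1L)
    }
  }
  paste(chars, collapse = "")
}

# random ancestral sequence, uniform base usage
random_sequence <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

#' Simulate a species-clustered barcode dataset
#'
#' A random ancestral sequence evolves along a three-level hierarchy:
#' family ancestors (deeper splits, so between-family divergence exceeds
#' between-species divergence), species ancestors placed so that two
#' samples of different same-family species are separated by
#' `inter_divergence` expected substitutions/site, and individual samples
#' perturbed so conspecific pairs are separated by `intra_divergence`.
#'
#' @param config A [barcode_sim_config()].
#' @return A list with `records` (data frame: id, seq, species, family,
#'   status) and `tree` (the generating species topology description).
#' @export
simulate_barcode_set <- function(config = barcode_sim_config()) {
  stopifnot(inherits(config, "barcode_sim_config"))
  set.seed(config$seed)
  kappa <- config$kappa
  b_sample <- config$intra_divergence / 2
  b_species <- (config$inter_divergence - config$intra_divergence) / 2
  b_family <- config$inter_divergence / 8  # extra depth above species level
  root <- random_sequence(config$seq_length)
  fam_of_sp <- sort(rep_len(seq_len(config$n_families), config$n_species))
  fam_anc <- lapply(seq_len(config$n_families), function(f)
    evolve_sequence(root, b_family, kappa))
  recs <- list()
  for (s in seq_len(config$n_species)) {
    sp_anc <- evolve_sequence(fam_anc[[fam_of_sp[s]]], b_species, kappa)
    for (k in seq_len(config$samples_per_species[s])) {
      recs[[length(recs) + 1L]] <- data.frame(
        id = sprintf("sp%02d_s%02d", s, k),
        seq = evolve_sequence(sp_anc, b_sample, kappa),
        species = sprintf("Species_%02d", s),
        family = sprintf("Family_%d", fam_of_sp[s]),
        status = "market", stringsAsFactors = FALSE)
    }
  }
  records <- do.call(rbind, recs)
  list(records = records,
       tree = list(family_of_species = fam_of_sp,
                   branch_sample = b_sample, branch_species = b_species,
                   branch_family = b_family))
}

#' Configuration for simulated HFP curves
#'
#' @param k_true Growth-rate constant (1/min).
#' @param P0_true Initial power (uW).
#' @param t_peak Time of the peak (min).
#' @param decay_rate Post-peak exponential decay rate (1/min).
#' @param noise_sd Additive Gaussian noise SD as a fraction of peak power.
#' @param duration Total duration (min), must exceed `t_peak`.
#' @param sampling_interval Sampling interval (min).
#' @param seed Integer seed.
#' @return A list of class `hfp_sim_config`.
#' @export
hfp_sim_config <- function(k_true = 0.05, P0_true = 2, t_peak = 60,
                           decay_rate = 0.03, noise_sd = 0.01,
                           duration = 120, sampling_interval = 1,
                           seed = 1L) {
  stopifnot(k_true > 0, P0_true > 0, t_peak > 0, decay_rate > 0,
            noise_sd >= 0, duration > t_peak, sampling_interval > 0)
  structure(list(k_true = k_true, P0_true = P0_true, t_peak = t_peak,
                 decay_rate = decay_rate, noise_sd = noise_sd,
                 duration = duration, sampling_interval = sampling_interval,
                 seed = as.integer(seed)),
            class = "hfp_sim_config")
}

#' Simulate a heat-flow power curve
#'
#' Exponential growth \eqn{P_0 e^{kt}} up to `t_peak`, then exponential
#' decay from the peak value; seeded additive Gaussian noise with SD equal
#' to `noise_sd` times the peak power.
#'
#' @param config An [hfp_sim_config()].
#' @param sample_id,group Labels attached to the curve.
#' @return An [hfp_curve()].
#' @export
simulate_hfp <- function(config = hfp_sim_config(), sample_id = "sim",
                         group = "control") {
  stopifnot(inherits(config, "hfp_sim_config"))
  set.seed(config$seed)
  t <- seq(0, config$duration, by = config$sampling_interval)
  p_peak <- config$P0_true * exp(config$k_true * config$t_peak)
  p <- ifelse(t <= config$t_peak,
              config$P0_true * exp(config$k_true * t),
              p_peak * exp(-config$decay_rate * (t - config$t_peak)))
  p <- p + stats::rnorm(length(t), 0, config$noise_sd * p_peak)
  hfp_curve(t, p, sample_id, group)
}
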