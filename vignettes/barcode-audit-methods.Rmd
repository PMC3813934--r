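---
title: "Methods: barcode authentication and thermokinetic screening of animal-derived medicinals"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: barcode authentication and thermokinetic screening of animal-derived medicinals}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(adtrace)
```

## The problem

Animal-derived medicinal materials — horns, antlers, turtle shells and
plastrons — reach the market ground into powders in which no morphological
character survives. Several source species are CITES-listed, and cheaper
domestic substitutes (goat or cattle horn, farmed turtle shell) circulate
under the same trade names. `adtrace` implements a desk-scale version of the
two-armed strategy used to police this trade: (1) molecular authentication of
market samples by a mitochondrial COI barcode, and (2) a functional screen by
isothermal microcalorimetry that quantifies how candidate substitutes modulate
metabolic heat output, so that pharmacological equivalence can be assessed
alongside identity.

## The barcode audit

### Amplicon model

All samples are amplified with one primer pair (defaults `MahF1`
5'-GCAGGAACAGGCTGAACCGT-3' and `MahR1` 5'-AATATGTGGTGGGCTCATAC-3') targeting a
477-bp stretch of COI. `crop_to_barcode()` performs the in-silico equivalent:
it scans every offset of a template for each primer (the reverse primer as its
reverse complement), keeps the hit with the fewest mismatches (ties go to the
leftmost position; `N` in the template always counts as a mismatch), and
excises the insert between the forward primer's 3' end and the reverse
binding site. Database sequences can be deposited in either orientation, so
if the forward strand fails the template's global reverse complement is
searched. By default the insert *excludes* the primer sequences — the region
actually sequenced — and no fixed amplicon length is enforced: the published
primer anchor coordinates and the nominal 477-bp length cannot all be
reconciled arithmetically, so a strict length check is an opt-in argument
(`expected_length`) rather than a hard-coded assertion.

### Alignment statistics

Cropped sequences from one amplicon share coordinates, so `build_alignment()`
simply stacks them (a general aligner is deliberately out of scope). Summary
statistics follow the conventions of the standard population-genetics and
distance software:

* **Complete deletion.** A column is *complete* iff no sequence has a gap or
  `N` there. Polymorphism counts, nucleotide diversity and haplotype
  identity are all computed over complete columns only, so every pairwise
  comparison shares one denominator. Whether the original desk analyses used
  pairwise or complete deletion for diversity is not documented; complete
  deletion is this package's recorded choice.
* **Base composition** averages per-sequence frequencies over scoreable bases
  (gaps/`N` out of the denominator), rather than pooling all bases — the
  convention that makes a mean AT-content comparable across sequences with
  unequal missing data.
* **`min_diagnostic_window()`** searches, exhaustively by ascending length
  and position, for the shortest contiguous run of columns in which every
  cross-species pair differs at a complete column. Degraded market DNA often
  yields only short fragments; a 20–30 bp diagnostic segment means a verdict
  is still possible. The non-contiguous variant of this search is a set-cover
  problem and is out of scope.

### Distances

`k2p_distance()` implements Kimura's two-parameter distance. With $S$ and $V$
the transition and transversion fractions over scored sites,

$$d = -\tfrac12 \ln\!\big[(1-2S-V)\sqrt{1-2V}\big].$$

The model separates the (much faster) purine–purine and pyrimidine–pyrimidine
exchanges from transversions and corrects for multiple hits; it is the de
facto standard for low-divergence barcode comparisons. Numerical edges:

* `n_scored = 0` (no shared unambiguous sites) is an error.
* Saturation ($1-2S-V \le 0$ or $1-2V \le 0$) is an error by default —
  an audit must not silently drop evidence — with an explicit
  `on_saturation = "na"` escape hatch at the matrix level.
* Default deletion policy is pairwise (each pair scored over its own shared
  sites), the usual default of distance software; a
  `complete-deletion-mask` policy is available and the audit report records
  which one produced its numbers.

### Divergence partition, barcoding gap and identification

`partition_divergence()` splits all $n(n-1)/2$ distances into intraspecific
and interspecific sets. The *barcoding gap* is present globally iff the
largest intraspecific distance is strictly below the smallest interspecific
one; per-species flags compare each species' maximal intraspecific distance
with its distance to the nearest non-conspecific. Singleton species have no
intraspecific pairs: their maximum is reported `NA`, excluded from the
overall maximum, and their gap flag (assessed against 0) is marked as coming
from a singleton.

`identify()` is a distance-based best-close-match rule: a query takes the
species of its nearest reference unless that distance exceeds the threshold
(`no_id`) or the nearest references tie across species (`ambiguous`; ties are
resolved at machine precision, $|\Delta d| < 10^{-12}$). The default
threshold of 0.02 substitutions/site sits in the empirically observed gap —
intraspecific divergences below about 1.8%, interspecific above about 2.0% —
and is configurable. `loo_identification()` removes each sequence in turn and
identifies it against the rest; queries whose species has no second
representative cannot possibly be scored correct and are excluded from the
success denominator (reported separately) rather than counted as failures.

### Trees

`nj_tree()` builds the neighbor-joining tree (Saitou–Nei agglomeration, via
`ape::nj`) on the K2P matrix. Negative branch lengths on non-additive input
are kept by default — silently clamping them would corrupt the path-length
recovery property that the test suite checks — with an explicit
`clamp_negative` option. `bootstrap_support()` resamples alignment columns
with replacement (seeded), rebuilds the tree per replicate, and scores each
internal edge of the original tree by the fraction of replicates containing
the same leaf bipartition; supports attach to bipartitions, not node
identities, so they are rooting-invariant. Replicates whose resampled matrix
saturates are skipped, warned about and reported. The replicate count is
configurable (1000 by default; the tests and examples use fewer).
`species_monophyly()` declares a species monophyletic iff some edge of the
unrooted tree separates exactly its leaves; with continuous distances, ties
in the agglomeration criterion are a measure-zero event, and all tested
configurations use generic matrices.

## The thermokinetic screen

Isothermal microcalorimetry records heat-flow power $P(t)$ (µW) of a
metabolising preparation (liver microsomes, lymphocytes) at constant
temperature. The growth phase obeys

$$P_t = P_0 e^{kt}, \qquad \ln P_t = \ln P_0 + kt,$$

so `fit_growth()` is an ordinary least-squares fit of $\ln P$ on $t$ over the
growth window, returned as a classed model object (`coef`, `predict`,
`residuals`, `plot`, `simulate` methods). The automatic window runs from the
first point reaching 10% of the peak up to the (first) peak — the source
protocol says only that $k$ is computed "from the data for the highest peak",
so the 10% floor is this package's explicit choice, recorded here; an
explicit `c(t_lo, t_hi)` window overrides it. A perfectly flat curve yields
slope 0 with a warning and an undefined $r^2$ (reported `NA`); nonpositive
power inside the window is an error, since the log is undefined.

`extract_params()` adds the peak power $P$, the time of the first maximal
point $t$, and total heat output $Q_t$ by trapezoidal integration.
`inhibition_ratio()` computes **both** published forms of the inhibition
statistic: the printed formula $I = (P^t - P^0)/k^0$ (peak-power difference
over the control rate constant — note its mixed units of µW·min) and the
dimensionless $I = (k^0 - k^t)/k^0$ that the accompanying prose ("calculated
from $k$") suggests. The two contradict each other in the source; rather than
adjudicate, the package reports both and lets `variant` mark the headline
one (printed, for fidelity, by default).

`pca_components()` standardises the parameter table ($k$, $P$, $t$, $Q_t$
carry incommensurate units, so the correlation matrix is the only defensible
choice) and eigendecomposes it; the *main components* are the smallest
leading set reaching a cumulative-variance cutoff (default 0.85). The
published figure of 91.89% for two components is not recomputable — no
parameter table was released — and is nowhere asserted.

## What the synthetic data emulate — and what they do not

No raw data ship with the package: the study's sequences live in GenBank
under accessions listed only in its supplement, and the calorimetry traces
were never released. The generators therefore reproduce the *statistical
shape* of the study design, and their defaults are fixed once:

* `simulate_barcode_set()`: 15 species in 4 families, 72 samples of 477 bp;
  expected within-species divergence 0.004 and between-species divergence
  0.158 substitutions/site — the study's reported means. Sequences evolve
  along a three-level hierarchy (family ancestors deeper than species
  ancestors, so between-family exceeds between-species divergence; the extra
  family depth is set to 1/8 of the interspecific divergence, a value chosen
  once to keep family clusters visibly deeper without approaching
  saturation). The substitution process is a per-site exponential
  waiting-time simulation under the two-parameter rate matrix with
  transition/transversion rate ratio $\kappa = 4$ (a typical mitochondrial
  value), so multiple hits genuinely occur and the K2P estimator's
  correction is exercised, not assumed.
* `simulate_hfp()`: exponential growth to a peak, exponential decay after
  it, additive Gaussian noise with SD a fixed fraction (default 1%) of the
  peak power. Defaults $k = 0.05$ min$^{-1}$, $P_0 = 2$ µW, peak at 60 min
  over a 120-min trace at 1-min sampling — magnitudes typical of microbial
  and organelle microcalorimetry.

What passing tests on these data show: the estimators invert the generating
process (simulated-then-estimated divergence is unbiased within Monte-Carlo
error for $d \le 0.3$; fitted $k$ recovers the generating constant within 2%
at 1% noise), the gap/identification logic behaves exactly as documented on
clean species structure, and the pipeline is deterministic given a seed.
What they do **not** show: real COI base composition and codon structure
(the generator's ancestral sequence is uniform-random), within-species
genealogy (no coalescent), indels (gap handling is tested with hand-placed
gaps), heteroplasmy, or the instrument drift and baseline artefacts of real
calorimetry. Results on real market surveys depend on reference-database
completeness in a way no simulation can certify.

## Problem sizes and numerical choices

The test suite and the reproduction script run everything at desk scale,
chosen as the package's own trade-off between statistical resolution and a
test suite that stays pleasant to run: 20 replicate surveys at the full
study shape (72 × 477), 200 random trees of 5–12 taxa for the NJ recovery
property, 50 seeds for noisy-$k$ recovery, 1000 random pairs for the K2P
closed-form check. Distance tolerances: exact identities to $10^{-12}$,
tree-length recovery to $10^{-9}$, Newick round-trips to $10^{-6}$ (branch
lengths are serialised at 6 decimals). JSON reports serialise numerics at 9
significant digits so identical runs are byte-identical.

## Known limitations

* Identification is a global-distance rule, not local alignment; it cannot
  flag chimeric sequences and never queries a live database.
* The NJ implementation targets small audit-scale matrices (tens to a few
  hundred taxa), not genome-scale phylogenetics.
* The diagnostic-window search is $O(L^2 \cdot \text{pairs})$ and intended
  for barcode-length alignments.
* The thermokinetic model assumes a single exponential growth phase; biphasic
  or lag-dominated curves need an explicit window.
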