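test_that("noiseless exponential growth is recovered exactly", {
  t <- 0:60
  cv <- hfp_curve(t, 2 * exp(0.05 * t))
  fit <- fit_growth(cv)
  expect_equal(fit$k, 0.05, tolerance = 1e-9)
  expect_equal(fit$P0, 2, tolerance = 1e-9)
  expect_equal(coef(fit), c(k = 0.05, P0 = 2), tolerance = 1e-9)
  expect_equal(predict(fit, 10), 2 * exp(0.5), tolerance = 1e-6)
})

test_that("k is recovered within 2% at 1% peak noise (median of 50 seeds)", {
  errs <- vapply(1:50, function(seed) {
    cv <- simulate_hfp(hfp_sim_config(noise_sd = 0.01, seed = seed))
    abs(fit_growth(cv)$k - 0.05) / 0.05
  }, numeric(1))
  expect_lte(median(errs), 0.02)
})

test_that("flat and degenerate curves are handled explicitly", {
  flat <- hfp_curve(0:20, rep(5, 21))
  expect_warning(fit <- fit_growth(flat), "flat")
  expect_equal(fit$k, 0)
  expect_true(is.na(fit$fit_r2))

  neg <- hfp_curve(0:20, c(-1, exp(0.1 * (1:20))))
  expect_error(fit_growth(neg, window = c(0, 20)), "nonpositive")
  expect_error(fit_growth(flat, window = c(0, 0.5)), "degenerate")
})

test_that("fit is scale-equivariant in power", {
  t <- 0:60
  set.seed(2)
  p <- 2 * exp(0.05 * t) + rnorm(61, 0, 0.1)
  f1 <- fit_growth(hfp_curve(t, p))
  f2 <- fit_growth(hfp_curve(t, 10 * p))
  expect_equal(f2$k, f1$k, tolerance = 1e-12)
  expect_equal(f2$P0, 10 * f1$P0, tolerance = 1e-9)
})

test_that("extract_params: triangle curve area and tie-breaks", {
  # rise 0 -> 10 uW over 10 min, fall back to 0 at 20 min
  tri <- hfp_curve(0:20, c(0:10, 9:0))
  par <- extract_params(tri)
  expect_equal(par$P_peak, 10)
  expect_equal(par$t_peak, 10)
  expect_equal(par$Q_total, 100)

  # two equal maxima: the earlier one wins
  two <- hfp_curve(0:12, c(0:5, 6, 5, 6, 4:1))
  expect_equal(extract_params(two)$t_peak, 6)
})

test_that("trapezoid integral is additive over subintervals", {
  set.seed(4)
  t <- sort(runif(30, 0, 100))
  p <- abs(rnorm(30, 10, 3))
  trap <- function(tt, pp) sum(diff(tt) * (pp[-1] + pp[-length(pp)]) / 2)
  mid <- 15
  expect_equal(trap(t, p), trap(t[1:mid], p[1:mid]) + trap(t[mid:30], p[mid:30]))
})

test_that("noiseless exponential-then-plateau Q matches the analytic integral", {
  k <- 0.05
  t <- seq(0, 100, by = 0.1)
  p <- ifelse(t <= 60, 2 * exp(k * t), 2 * exp(k * 60))
  cv <- hfp_curve(t, p)
  analytic <- (2 / k) * (exp(k * 60) - 1) + 40 * 2 * exp(k * 60)
  expect_equal(extract_params(cv)$Q_total, analytic, tolerance = 1e-4)
})

test_that("inhibition ratio computes both variants", {
  ctrl <- make_params(k = 0.05, P_peak = 10)
  same <- inhibition_ratio(ctrl, ctrl)
  expect_equal(same$I_printed, 0)
  expect_equal(same$I_k_variant, 0)

  treated <- make_params(k = 0.02, P_peak = 5)
  res <- inhibition_ratio(treated, ctrl)
  expect_equal(res$I_printed, (5 - 10) / 0.05)  # -100
  expect_equal(res$I_k_variant, (0.05 - 0.02) / 0.05)  # 0.6
  expect_equal(res$variant_used, "printed")

  expect_error(inhibition_ratio(treated, make_params(0, 10)), "0")
})

test_that("PCA components: conservation, correlation limit, selection", {
  set.seed(6)
  x <- rnorm(100)
  two <- data.frame(a = x, b = 3 * x + 1)  # perfectly correlated
  pc <- pca_components(two)
  expect_equal(unname(pc$variance_explained[1]), 1.0, tolerance = 1e-12)
  expect_equal(pc$selected, "PC1")

  four <- as.data.frame(matrix(rnorm(4000), 1000, 4))
  ve <- pca_components(four)$variance_explained
  expect_true(all(abs(ve - 0.25) < 0.05))
  expect_equal(sum(ve), 1, tolerance = 1e-9)

  rand <- as.data.frame(matrix(rnorm(60), 12, 5))
  expect_equal(sum(pca_components(rand)$variance_explained), 1,
               tolerance = 1e-9)

  bad <- data.frame(a = rnorm(10), b = rep(2, 10))
  expect_error(pca_components(bad), "b")
  expect_error(pca_components(rand[1:2, ]), "3 samples")
})

test_that("PCA is invariant to sample order and affine column rescaling", {
  set.seed(8)
  tab <- as.data.frame(matrix(rnorm(200), 50, 4))
  ve <- pca_components(tab)$variance_explained
  perm <- tab[sample(50), ]
  expect_equal(pca_components(perm)$variance_explained, ve,
               tolerance = 1e-9)
  scaled <- tab
  scaled[[2]] <- 100 * scaled[[2]] - 7
  expect_equal(pca_components(scaled)$variance_explained, ve,
               tolerance = 1e-9)
})

test_that("hfp_curve validates its invariants", {
  expect_error(hfp_curve(1:5, 1:5), "10 points")
  expect_error(hfp_curve(c(1:10, 10), 1:11), "increasing")
  expect_error(hfp_curve(1:10, c(1:9, NA)), "NaN|NA")
})

test_that("HFP CSV round-trip preserves curves", {
  cv <- simulate_hfp(hfp_sim_config(seed = 3), sample_id = "m1",
                     group = "treated:antler")
  f <- tempfile(fileext = ".csv")
  write.csv(data.frame(time_min = cv$times, power_uW = cv$power,
                       sample_id = cv$sample_id, group = cv$group),
            f, row.names = FALSE)
  back <- read_hfp_csv(f)
  expect_equal(names(back), "m1")
  expect_equal(back$m1$power, cv$power, tolerance = 1e-9)
  expect_equal(back$m1$group, "treated:antler")
})
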