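#' Construct a heat-flow power curve
#'
#' A time series of heat-flow power (HFP) from isothermal microcalorimetry,
#' tracking metabolic heat output of a sample (e.g. liver microsomes or
#' lymphocytes) at constant temperature.
#'
#' @param times Time points in minutes, strictly increasing.
#' @param power HFP values in microwatts, same length.
#' @param sample_id Sample identifier.
#' @param group `"control"` or a treatment label (e.g. `"treated:antler"`).
#' @return An object of class `hfp_curve`.
#' @export
hfp_curve <- function(times, power, sample_id = "sample",
                      group = "control") {
  times <- as.numeric(times); power <- as.numeric(power)
  if (length(times) != length(power)) stop("times and power lengths differ")
  if (length(times) < 10L) stop("an HFP curve needs at least 10 points")
  if (anyNA(times) || anyNA(power)) stop("NaN/NA in curve")
  if (any(diff(times) <= 0)) stop("times must be strictly increasing")
  structure(list(times = times, power = power, sample_id = sample_id,
                 group = group), class = "hfp_curve")
}

#' @export
print.hfp_curve <- function(x, ...) {
  cat("HFP curve '", x$sample_id, "' (", x$group, "): ",
      length(x$times), " points, t = [", min(x$times), ", ", max(x$times),
      "] min, peak ", sprintf("%.3g", max(x$power)), " uW\n", sep = "")
  invisible(x)
}

#' Read HFP curves from CSV
#'
#' Expects columns `time_min`, `power_uW`, `sample_id`, `group`.
#'
#' @param path CSV path.
#' @return A list of [hfp_curve()] objects, one per sample id.
#' @export
read_hfp_csv <- function(path) {
  df <- utils::read.delim(path, sep = ",", header = TRUE,
                          stringsAsFactors = FALSE)
  need <- c("time_min", "power_uW", "sample_id", "group")
  if (!all(need %in% names(df)))
    stop("HFP CSV must have columns: ", paste(need, collapse = ", "))
  lapply(split(df, df$sample_id), function(d) {
    d <- d[order(d$time_min), ]
    hfp_curve(d$time_min, d$power_uW, d$sample_id[1L], d$group[1L])
  })
}

#' Fit the exponential growth phase of an HFP curve
#'
#' The growth phase follows \eqn{P_t = P_0 e^{kt}}, i.e.
#' \eqn{\ln P_t = \ln P_0 + kt}; the fit is an ordinary least-squares
#' regression of \eqn{\ln(\mathrm{power})} on time over the growth window.
#' The automatic window runs from the first point reaching 10% of the peak
#' power up to the time of the (first) peak.
#'
#' @param curve An [hfp_curve()].
#' @param window `"auto"`, or a numeric `c(t_lo, t_hi)` in minutes.
#' @return An object of class `thermo_fit` with components `k` (1/min),
#'   `P0` (uW), `fit_r2`, the window used, and the underlying `lm` fit.
#'   Supports `coef`, `summary`, `predict`, `residuals`, `plot`,
#'   `simulate`.
#' @export
fit_growth <- function(curve, window = "auto") {
  stopifnot(inherits(curve, "hfp_curve"))
  t <- curve$times; p <- curve$power
  if (identical(window, "auto")) {
    peak <- which.max(p)
    lo <- which(p >= 0.1 * p[peak])[1L]
    idx <- lo:peak
    if (length(idx) < 3L && stats::var(p) == 0) idx <- seq_along(p)
  } else {
    stopifnot(is.numeric(window), length(window) == 2L)
    idx <- which(t >= window[1L] & t <= window[2L])
  }
  if (length(idx) < 3L)
    stop("degenerate growth window (fewer than 3 points)")
  if (any(p[idx] <= 0))
    stop("nonpositive power inside growth window: log undefined")
  tw <- t[idx]; lw <- log(p[idx])
  if (stats::var(lw) == 0) {
    warning("flat curve in growth window: slope 0, r2 undefined")
    fit <- stats::lm(lw ~ tw)
    k <- 0; P0 <- exp(lw[1L]); r2 <- NA_real_
  } else {
    fit <- stats::lm(lw ~ tw)
    k <- unname(stats::coef(fit)[2L])
    P0 <- exp(unname(stats::coef(fit)[1L]))
    r2 <- suppressWarnings(summary(fit)$r.squared)
  }
  structure(list(k = k, P0 = P0, fit_r2 = r2,
                 window = range(tw), n_points = length(idx),
                 lm_fit = fit, curve = curve),
            class = "thermo_fit")
}

#' @export
print.thermo_fit <- function(x, ...) {
  cat("Exponential growth-phase fit (ln P = ln P0 + k t)\n")
  cat(sprintf("  k  = %.5g 1/min\n  P0 = %.5g uW\n  r2 = %s  (%d points, t in [%.3g, %.3g] min)\n",
              x$k, x$P0, if (is.na(x$fit_r2)) "NA" else sprintf("%.4f", x$fit_r2),
              x$n_points, x$window[1L], x$window[2L]))
  invisible(x)
}

#' @export
coef.thermo_fit <- function(object, ...) c(k = object$k, P0 = object$P0)

#' @export
summary.thermo_fit <- function(object, ...) {
  print(object)
  invisible(object)
}

#' @export
predict.thermo_fit <- function(object, times = NULL, ...) {
  if (is.null(times)) times <- object$curve$times
  object$P0 * exp(object$k * times)
}

#' @export
residuals.thermo_fit <- function(object, ...) {
  stats::residuals(object$lm_fit)
}

#' @export
plot.thermo_fit <- function(x, ...) {
  plot(x$curve$times, x$curve$power, xlab = "time (min)",
       ylab = "heat-flow power (uW)",
       main = paste("HFP curve:", x$curve$sample_id), ...)
  tt <- seq(x$window[1L], x$window[2L], length.out = 100L)
  graphics::lines(tt, predict(x, tt), lwd = 2)
  graphics::abline(v = x$window, lty = 3)
  invisible(x)
}

#' @export
simulate.thermo_fit <- function(object, nsim = 1, seed = NULL,
                                noise_sd = 0.01, ...) {
  if (!is.null(seed)) set.seed(seed)
  peak <- max(predict(object))
  replicate(nsim, predict(object) +
              stats::rnorm(length(object$curve$times), 0, noise_sd * peak),
            simplify = FALSE)
}

#' Extract thermokinetic parameters from an HFP curve
#'
#' Peak power `P_peak`, time of the (first) peak `t_peak`, total heat
#' output `Q_total` by trapezoidal integration of power over time, and the
#' growth-phase constants `k`, `P0`, `fit_r2` from [fit_growth()].
#'
#' @param curve An [hfp_curve()].
#' @param window Growth window passed to [fit_growth()].
#' @return An object of class `thermo_params` (a named list).
#' @export
extract_params <- function(curve, window = "auto") {
  stopifnot(inherits(curve, "hfp_curve"))
  t <- curve$times; p <- curve$power
  peak <- which.max(p)  # first maximum on ties
  q_total <- sum(diff(t) * (p[-1L] + p[-length(p)]) / 2)
  fit <- fit_growth(curve, window)
  structure(list(sample_id = curve$sample_id, group = curve$group,
                 k = fit$k, P0 = fit$P0, fit_r2 = fit$fit_r2,
                 P_peak = p[peak], t_peak = t[peak], Q_total = q_total),
            class = "thermo_params")
}

#' @export
print.thermo_params <- function(x, ...) {
  cat(sprintf("Thermokinetic parameters for '%s' (%s):\n", x$sample_id,
              x$group))
  cat(sprintf("  k = %.5g 1/min, P0 = %.5g uW, r2 = %s\n", x$k, x$P0,
              if (is.na(x$fit_r2)) "NA" else sprintf("%.4f", x$fit_r2)))
  cat(sprintf("  P_peak = %.5g uW at t_peak = %.5g min; Q_total = %.5g uW*min\n",
              x$P_peak, x$t_peak, x$Q_total))
  invisible(x)
}

#' Inhibition ratio of a treatment on metabolic heat output
#'
#' Two variants are always computed. The `printed` variant is
#' \eqn{I = (P^t - P^0)/k^0} — the peak-power difference between treated
#' and control, scaled by the control growth-rate constant (note its mixed
#' units of uW.min). The `k_based` variant is the dimensionless relative
#' suppression of the growth-rate constant,
#' \eqn{I = (k^0 - k^t)/k^0}. `variant` marks which is the headline
#' number; both are reported.
#'
#' @param treated,control [extract_params()] results.
#' @param variant `"printed"` (default) or `"k_based"`.
#' @return A list with `I_printed`, `I_k_variant`, `variant_used`.
#' @export
inhibition_ratio <- function(treated, control,
                             variant = c("printed", "k_based")) {
  variant <- match.arg(variant)
  stopifnot(inherits(treated, "thermo_params"),
            inherits(control, "thermo_params"))
  if (control$k == 0) stop("control growth-rate constant is 0")
  list(I_printed = (treated$P_peak - control$P_peak) / control$k,
       I_k_variant = (control$k - treated$k) / control$k,
       variant_used = variant)
}

#' Principal components of a thermokinetic parameter table
#'
#' Columns (e.g. `k`, `P_peak`, `t_peak`, `Q_total`) are standardised to
#' zero mean and unit variance — they carry incommensurate units — and the
#' correlation matrix is eigendecomposed. The smallest leading set of
#' components whose cumulative variance reaches `cutoff` is selected as the
#' main components.
#'
#' @param param_table Numeric data frame or matrix, samples x parameters.
#' @param cutoff Cumulative-variance cutoff (default 0.85).
#' @return A list with `loadings` (variables x components),
#'   `variance_explained` (fractions summing to 1), `cumulative`, and
#'   `selected` (names of the main components).
#' @export
pca_components <- function(param_table, cutoff = 0.85) {
  x <- as.matrix(param_table)
  if (nrow(x) < 3L) stop("need at least 3 samples")
  if (anyNA(x)) stop("missing values in parameter table")
  sds <- apply(x, 2L, stats::sd)
  if (any(sds == 0))
    stop("zero-variance column(s): ",
         paste(colnames(x)[sds == 0], collapse = ", "))
  pc <- stats::prcomp(x, center = TRUE, scale. = TRUE)
  ve <- pc$sdev^2 / sum(pc$sdev^2)
  names(ve) <- colnames(pc$rotation)
  cum <- cumsum(ve)
  n_sel <- which(cum >= cutoff)[1L]
  list(loadings = pc$rotation, variance_explained = ve,
       cumulative = cum, selected = names(ve)[seq_len(n_sel)])
}
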