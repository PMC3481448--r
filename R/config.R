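#' Pipeline run configuration
#'
#' Collects every tunable parameter of the simulated LC-MS workflow in one
#' validated list, with defaults matching the reference configuration of the
#' model (two classes, 50 samples each, 20 markers over 500 background
#' proteins, Gamma(2, 1000) concentrations, block correlation 0.6 in blocks of
#' 2, fold changes Unif(1.5, 2), efficiency Unif(0.1, 1), instrument response
#' 5, no saturation, noise alpha = 0.03 / beta = 3.6, detection curve
#' TPR = 0.0016 SNR^2, one MS2 replicate).
#'
#' @param M Samples per class (two classes are simulated).
#' @param n_markers Number of differentially expressed marker proteins.
#' @param n_background Number of non-marker background proteins.
#' @param t,theta Shape and scale of the Gamma law of control protein means.
#' @param a_lo,a_hi Bounds of the uniform fold-change magnitude (both > 1).
#' @param rho Within-block correlation of protein sample variation.
#' @param D Correlation block size.
#' @param phi Coefficient of variation: per-protein sample standard deviation
#'   is `phi` times the control mean.
#' @param marker_quantile_cap Optional upper Gamma quantile for marker means
#'   (e.g. 0.25 restricts markers to the lowest abundance quartile); `NULL`
#'   disables the cap.
#' @param e_lo,e_hi Bounds of the uniform per-peptide efficiency factor.
#' @param kappa Instrument response factor converting concentration to ion
#'   abundance.
#' @param sat Detector saturation ceiling on expected abundance (`Inf` for a
#'   purely linear instrument).
#' @param alpha,beta Noise coefficients: abundance variance is
#'   `alpha * mu^2 + beta * mu`.
#' @param k,p,b MS1 detection curve: TPR = `k * SNR^p + b`, clamped to
#'   \[0, 1\].
#' @param overlap_aware If `TRUE`, the detection algorithm is robust to
#'   overlapping peptide signals (overlap factor 1); if `FALSE`, TPR is
#'   divided by the number of peptides sharing a mass/RT neighbourhood.
#' @param perfect_detection If `TRUE`, TPR is 1 wherever SNR > 0 (used to
#'   isolate noise effects from detection-algorithm effects).
#' @param mass_resolution Mass resolving power used by the overlap rule.
#' @param n_scans Number of LC scans; retention times live in (0, n_scans).
#' @param rt_tol_frac Retention-time closeness threshold as a fraction of
#'   `n_scans`.
#' @param n_ms2_replicates Number of replicate MS2 assays per sample.
#' @param identifiability Identifiability model: `list(model = "beta",
#'   shape1, shape2)` for a seeded Beta draw per peptide species,
#'   `list(model = "logistic")` for a deterministic logistic in peptide
#'   length and hydropathy, or `list(model = "fixed", value)` for a
#'   constant.
#' @param missed_cleavages,min_length,max_length Tryptic digestion settings.
#' @param max_missing_rate,min_corr,min_peptides,unique_only Roll-up filter
#'   thresholds.
#' @param alpha_level Significance level of the per-protein t-test.
#' @param n_features Number of top differentially expressed features kept for
#'   classification.
#' @param knn_k Neighbour count of the KNN classifier (odd).
#' @param n_test_per_class Independent test samples per class used to measure
#'   classification error.
#' @return A validated list of class `pipesim_config`.
#' @examples
#' cfg <- sim_config(M = 10, n_background = 50, n_markers = 5)
#' cfg$kappa
#' @export
sim_config <- function(M = 50,
                       n_markers = 20,
                       n_background = 500,
                       t = 2,
                       theta = 1000,
                       a_lo = 1.5,
                       a_hi = 2,
                       rho = 0.6,
                       D = 2,
                       phi = 0.1,
                       marker_quantile_cap = NULL,
                       e_lo = 0.1,
                       e_hi = 1,
                       kappa = 5,
                       sat = Inf,
                       alpha = 0.03,
                       beta = 3.6,
                       k = 0.0016,
                       p = 2,
                       b = 0,
                       overlap_aware = TRUE,
                       perfect_detection = FALSE,
                       mass_resolution = 50000,
                       n_scans = 1000,
                       rt_tol_frac = 0.005,
                       n_ms2_replicates = 1,
                       identifiability = list(model = "beta", shape1 = 2,
                                              shape2 = 8),
                       missed_cleavages = 0,
                       min_length = 6,
                       max_length = 40,
                       max_missing_rate = 0.7,
                       min_corr = 0.6,
                       min_peptides = 2,
                       unique_only = TRUE,
                       alpha_level = 0.05,
                       n_features = 20,
                       knn_k = 3,
                       n_test_per_class = 1000) {
  cfg <- list(
    M = check_count(M, "M", 2L),
    n_markers = check_count(n_markers, "n_markers", 1L),
    n_background = check_count(n_background, "n_background", 1L),
    t = check_scalar(t, "t", lower = 1e-12),
    theta = check_scalar(theta, "theta", lower = 1e-12),
    a_lo = check_scalar(a_lo, "a_lo"),
    a_hi = check_scalar(a_hi, "a_hi"),
    rho = check_scalar(rho, "rho", lower = 0, upper = 1 - 1e-12),
    D = check_count(D, "D", 1L),
    phi = check_scalar(phi, "phi", lower = 1e-12),
    marker_quantile_cap = marker_quantile_cap,
    e_lo = check_scalar(e_lo, "e_lo", lower = 1e-12, upper = 1),
    e_hi = check_scalar(e_hi, "e_hi", lower = 1e-12, upper = 1),
    kappa = check_scalar(kappa, "kappa", lower = 1e-12),
    sat = check_scalar(sat, "sat", lower = 1e-12, allow_inf = TRUE),
    alpha = check_scalar(alpha, "alpha", lower = 0),
    beta = check_scalar(beta, "beta", lower = 0),
    k = check_scalar(k, "k", lower = 0),
    p = check_scalar(p, "p", lower = 1e-12),
    b = check_scalar(b, "b", lower = 0, upper = 1),
    overlap_aware = isTRUE(overlap_aware),
    perfect_detection = isTRUE(perfect_detection),
    mass_resolution = check_scalar(mass_resolution, "mass_resolution",
                                   lower = 1e-12),
    n_scans = check_count(n_scans, "n_scans", 1L),
    rt_tol_frac = check_scalar(rt_tol_frac, "rt_tol_frac", lower = 0,
                               upper = 1),
    n_ms2_replicates = check_count(n_ms2_replicates, "n_ms2_replicates", 1L),
    identifiability = identifiability,
    missed_cleavages = check_count(missed_cleavages, "missed_cleavages", 0L),
    min_length = check_count(min_length, "min_length", 1L),
    max_length = check_count(max_length, "max_length", 1L),
    max_missing_rate = check_scalar(max_missing_rate, "max_missing_rate",
                                    lower = 0, upper = 1),
    min_corr = check_scalar(min_corr, "min_corr", lower = 0, upper = 1),
    min_peptides = check_count(min_peptides, "min_peptides", 1L),
    unique_only = isTRUE(unique_only),
    alpha_level = check_scalar(alpha_level, "alpha_level", lower = 1e-12,
                               upper = 1 - 1e-12),
    n_features = check_count(n_features, "n_features", 1L),
    knn_k = check_count(knn_k, "knn_k", 1L),
    n_test_per_class = check_count(n_test_per_class, "n_test_per_class", 1L)
  )
  if (cfg$a_lo <= 1 || cfg$a_hi < cfg$a_lo) {
    abort("fold-change bounds need 1 < a_lo <= a_hi")
  }
  if (cfg$e_hi < cfg$e_lo) abort("`e_hi` must be >= `e_lo`")
  if (!is.null(cfg$marker_quantile_cap)) {
    check_scalar(cfg$marker_quantile_cap, "marker_quantile_cap",
                 lower = 1e-12, upper = 1)
  }
  if (cfg$alpha == 0 && cfg$beta == 0 && !cfg$perfect_detection) {
    # noiseless mode is allowed; SNR is infinite so the TPR curve saturates
    NULL
  }
  if (cfg$knn_k %% 2L == 0L) abort("`knn_k` must be odd")
  if (cfg$max_length < cfg$min_length) {
    abort("`max_length` must be >= `min_length`")
  }
  if (!is.list(cfg$identifiability) ||
      !cfg$identifiability$model %in% c("beta", "logistic", "fixed")) {
    abort("`identifiability$model` must be \"beta\", \"logistic\" or \"fixed\"")
  }
  structure(cfg, class = "pipesim_config")
}

#' @export
print.pipesim_config <- function(x, ...) {
  cat("<pipesim_config>\n")
  cat(sprintf("  design: %d + %d proteins, M = %d per class\n",
              x$n_markers, x$n_background, x$M))
  cat(sprintf("  abundance: Gamma(%g, %g), rho = %g (D = %d), phi = %g\n",
              x$t, x$theta, x$rho, x$D, x$phi))
  cat(sprintf("  signal: e ~ U(%g, %g), kappa = %g, sat = %g, alpha = %g, beta = %g\n",
              x$e_lo, x$e_hi, x$kappa, x$sat, x$alpha, x$beta))
  cat(sprintf("  detection: TPR = %g * SNR^%g + %g, overlap_aware = %s, MS2 reps = %d\n",
              x$k, x$p, x$b, x$overlap_aware, x$n_ms2_replicates))
  invisible(x)
}
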