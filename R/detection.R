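# MS1 peptide detection (SNR- and overlap-dependent TPR), MS2 identification
# (Bernoulli identifiability with replicates), and their AND-linking.

#' Signal-to-noise ratio of expected abundances
#'
#' SNR is squared expected signal over noise variance:
#' `mu^2 / (alpha mu^2 + beta mu) = mu / (alpha mu + beta)`. It is zero at
#' zero signal, increases with signal strength, and approaches `1/alpha` for
#' strong signals. With `alpha = beta = 0` (noiseless instrument) the SNR is
#' infinite wherever there is signal.
#'
#' @param mu Expected abundance matrix (non-negative).
#' @param alpha,beta Noise coefficients as in [add_noise()].
#' @return SNR matrix, same shape as `mu`.
#' @export
snr <- function(mu, alpha = 0.03, beta = 3.6) {
  if (any(mu < 0)) abort("`mu` must be non-negative")
  if (alpha == 0 && beta == 0) {
    out <- array(0, dim = dim(mu) %||% length(mu))
    out[mu > 0] <- Inf
  } else {
    out <- mu / (alpha * mu + beta)
    out[mu == 0] <- 0                # covers 0/0 when beta = 0
  }
  dim(out) <- dim(mu)
  dimnames(out) <- dimnames(mu)
  out
}

#' Count overlapping peptide signals
#'
#' Two peptide species overlap when their masses are closer than the
#' instrument's resolving power and their retention times are closer than a
#' fixed fraction of the LC run:
#' `|m2 - m1| / min(m1, m2) < 1 / mass_resolution` and
#' `|rt1 - rt2| / n_scans < rt_tol_frac`. The count for a peptide includes
#' itself, so an isolated peptide has count 1 and an n-way clash gives n.
#'
#' @param catalog A digested `proteome_catalog`.
#' @param mass_resolution Mass resolving power.
#' @param n_scans LC scan count.
#' @param rt_tol_frac Retention-time closeness threshold (fraction of scans).
#' @return Integer vector of overlap counts, one per peptide species in
#'   catalog order.
#' @export
overlap_counts <- function(catalog, mass_resolution = 50000, n_scans = 1000,
                           rt_tol_frac = 0.005) {
  stopifnot(inherits(catalog, "proteome_catalog"))
  if (catalog$n_pep == 0L) abort("catalog has no peptides")
  mass <- catalog$peptides$mono_mass
  rt <- catalog$peptides$rt
  n <- length(mass)
  ord <- order(mass)
  m_s <- mass[ord]
  rt_s <- rt[ord]
  counts <- rep(1L, n)
  rt_tol <- rt_tol_frac * n_scans
  # scan upward from each peptide: relative mass gap uses the smaller mass
  hi <- findInterval(m_s * (1 + 1 / mass_resolution), m_s)
  for (i in seq_len(n - 1L)) {
    if (hi[i] <= i) next
    js <- (i + 1L):hi[i]
    # strict inequality on the mass criterion
    js <- js[(m_s[js] - m_s[i]) / m_s[i] < 1 / mass_resolution &
               abs(rt_s[js] - rt_s[i]) < rt_tol]
    if (length(js) > 0) {
      counts[ord[i]] <- counts[ord[i]] + length(js)
      counts[ord[js]] <- counts[ord[js]] + 1L
    }
  }
  counts
}

#' MS1 detection true positive rate
#'
#' The base rate is a polynomial in SNR, `k * SNR^p + b`, clamped to
#' \[0, 1\]. Overlap-aware detection algorithms keep the base rate; overlap-
#' sensitive algorithms divide it by the number of overlapping peptide
#' signals. With `perfect_detection`, TPR is 1 wherever SNR > 0 and 0
#' elsewhere.
#'
#' @param snr_matrix SNR matrix from [snr()].
#' @param overlap Per-peptide overlap counts from [overlap_counts()] (or 1).
#' @param k,p,b Curve parameters.
#' @param overlap_aware Logical, see [sim_config()].
#' @param perfect_detection Logical, see [sim_config()].
#' @return TPR matrix in \[0, 1\].
#' @export
tpr <- function(snr_matrix, overlap = 1, k = 0.0016, p = 2, b = 0,
                overlap_aware = TRUE, perfect_detection = FALSE) {
  if (any(snr_matrix < 0)) abort("SNR must be non-negative")
  if (perfect_detection) {
    out <- (snr_matrix > 0) * 1
  } else {
    base <- k * snr_matrix^p + b
    base[is.infinite(snr_matrix)] <- if (k > 0) 1 else b
    base[base > 1] <- 1
    base[base < 0] <- 0
    o <- if (overlap_aware) 1 else 1 / overlap
    out <- base * o
  }
  dim(out) <- dim(snr_matrix)
  dimnames(out) <- dimnames(snr_matrix)
  out
}

#' Realize MS1 detection as Bernoulli trials
#'
#' @param tpr_matrix TPR matrix in \[0, 1\].
#' @param seed Integer seed.
#' @return Logical matrix of detected cells.
#' @export
detect_ms1 <- function(tpr_matrix, seed = NULL) {
  if (any(tpr_matrix < 0 | tpr_matrix > 1)) abort("TPR must lie in [0, 1]")
  with_seed(seed, {
    d <- runif(length(tpr_matrix)) < tpr_matrix
    dim(d) <- dim(tpr_matrix)
    dimnames(d) <- dimnames(tpr_matrix)
    d
  })
}

#' Assign per-peptide MS2 identifiability
#'
#' The probability that a peptide species is identified by MS2 database
#' search in one assay. Two stand-in models are provided: a seeded
#' `Beta(shape1, shape2)` draw per species (default Beta(2, 8), mean 0.2),
#' and a deterministic logistic in peptide length and hydropathy for
#' reproducibility studies.
#'
#' @param catalog A digested `proteome_catalog`.
#' @param model `list(model = "beta", shape1, shape2)`,
#'   `list(model = "logistic")`, or `list(model = "fixed", value)` for a
#'   constant identifiability (e.g. 1 in idealized identification settings).
#' @param seed Integer seed (ignored by the deterministic model).
#' @return Numeric vector of identifiabilities in \[0, 1\].
#' @export
assign_identifiability <- function(catalog,
                                   model = list(model = "beta", shape1 = 2,
                                                shape2 = 8),
                                   seed = NULL) {
  stopifnot(inherits(catalog, "proteome_catalog"))
  if (catalog$n_pep == 0L) abort("catalog has no peptides")
  name <- model$model
  if (identical(name, "beta")) {
    with_seed(seed,
              rbeta(catalog$n_pep, model$shape1 %||% 2, model$shape2 %||% 8))
  } else if (identical(name, "logistic")) {
    g <- gravy_score(catalog$peptides$sequence)
    len <- catalog$peptides$length
    plogis(-1.4 + 0.8 * g - 0.04 * (len - 15))
  } else if (identical(name, "fixed")) {
    val <- check_scalar(model$value %||% 1, "identifiability value",
                        lower = 0, upper = 1)
    rep(val, catalog$n_pep)
  } else {
    abort(sprintf("unknown identifiability model: %s", name))
  }
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Realize MS2 identification with replicate assays
#'
#' A peptide species in a sample is identified when at least one of
#' `n_replicates` independent Bernoulli trials with its identifiability
#' succeeds; equivalently a single trial with success rate
#' `1 - (1 - p_i)^r`. Identification is drawn independently per sample.
#'
#' @param p_i Per-peptide identifiability vector.
#' @param n_samples Number of samples (columns).
#' @param n_replicates Number of replicate MS2 assays.
#' @param seed Integer seed.
#' @return Logical matrix (peptides x samples) of identified cells.
#' @export
identify_ms2 <- function(p_i, n_samples, n_replicates = 1, seed = NULL) {
  if (any(p_i < 0 | p_i > 1)) abort("identifiability must lie in [0, 1]")
  check_count(n_samples, "n_samples", 1L)
  check_count(n_replicates, "n_replicates", 1L)
  prob <- 1 - (1 - p_i)^n_replicates
  with_seed(seed, {
    m <- matrix(runif(length(p_i) * n_samples), nrow = length(p_i)) < prob
    m
  })
}

#' Link MS1 detection and MS2 identification results
#'
#' A peptide feature is treated as observed only when reported by both the
#' MS1 detection algorithm and the MS2 search — the AND of the two masks.
#' This confrontation of two orthogonal evidence streams is what suppresses
#' false positives in the modeled workflow.
#'
#' @param detected Logical MS1 mask.
#' @param identified Logical MS2 mask.
#' @param v Noisy abundance matrix.
#' @param identifiability Optional per-peptide identifiability (carried
#'   through for reporting).
#' @param overlap Optional per-peptide overlap counts (carried through).
#' @return An `observed_peptide_table`: list with `detected`, `identified`,
#'   `observed` (= detected & identified), `abundance` (v where observed,
#'   `NA` otherwise), `identifiability`, `overlap_count`.
#' @export
link_observations <- function(detected, identified, v,
                              identifiability = NULL, overlap = NULL) {
  if (!identical(dim(detected), dim(identified)) ||
      !identical(dim(detected), dim(v))) {
    abort("`detected`, `identified` and `v` must have identical shape")
  }
  observed <- detected & identified
  abundance <- v
  abundance[!observed] <- NA_real_
  structure(
    list(detected = detected, identified = identified, observed = observed,
         abundance = abundance, identifiability = identifiability,
         overlap_count = overlap),
    class = "observed_peptide_table"
  )
}

#' @export
print.observed_peptide_table <- function(x, ...) {
  cat(sprintf(
    "<observed_peptide_table> %d peptides x %d samples; observed cells: %.1f%%\n",
    nrow(x$observed), ncol(x$observed), 100 * mean(x$observed)))
  invisible(x)
}
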