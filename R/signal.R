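# Peptide signal model: protein-to-peptide concentration roll-down, peptide
# efficiency, instrument response, saturation, and signal-dependent noise.

#' Peptide concentrations from protein concentrations
#'
#' The concentration of a peptide species in a sample is the sum of the
#' concentrations of every protein containing it (shared peptides pool their
#' parents' contributions).
#'
#' @param catalog A digested `proteome_catalog`.
#' @param conc_pro Protein concentration matrix (proteins x samples) with
#'   rownames matching catalog protein ids, or a `ground_truth_samples`
#'   object.
#' @return Peptide concentration matrix (n_pep x samples).
#' @export
peptide_concentrations <- function(catalog, conc_pro) {
  stopifnot(inherits(catalog, "proteome_catalog"))
  if (inherits(conc_pro, "ground_truth_samples")) {
    conc_pro <- conc_pro$concentrations
  }
  if (catalog$n_pep == 0L) abort("catalog has no peptides; run digest() first")
  parent_ids <- unlist(catalog$peptides$parents)
  row_idx <- rep(seq_len(catalog$n_pep), catalog$peptides$n_parents)
  col_idx <- match(parent_ids, rownames(conc_pro))
  if (anyNA(col_idx)) {
    abort("peptide parent protein(s) missing from the concentration matrix")
  }
  c_pep <- matrix(0, nrow = catalog$n_pep, ncol = ncol(conc_pro),
                  dimnames = list(catalog$peptides$peptide_id,
                                  colnames(conc_pro)))
  # accumulate parent rows into peptide rows
  grouped <- rowsum(conc_pro[col_idx, , drop = FALSE], group = row_idx)
  c_pep[as.integer(rownames(grouped)), ] <- grouped
  c_pep
}

#' Draw per-peptide efficiency factors
#'
#' One efficiency per peptide species, i.i.d. Unif(e_lo, e_hi), fixed across
#' all samples and classes. The efficiency lumps LC transmission, ionization
#' efficiency and related losses into a single factor.
#'
#' @param n_pep Number of peptide species (or a digested catalog).
#' @param e_lo,e_hi Uniform bounds in (0, 1].
#' @param seed Integer seed.
#' @return Numeric vector of efficiencies.
#' @export
draw_efficiencies <- function(n_pep, e_lo = 0.1, e_hi = 1, seed = NULL) {
  if (inherits(n_pep, "proteome_catalog")) n_pep <- n_pep$n_pep
  check_count(n_pep, "n_pep", 1L)
  if (e_lo <= 0 || e_hi > 1 || e_hi < e_lo) {
    abort("need 0 < e_lo <= e_hi <= 1")
  }
  with_seed(seed, runif(n_pep, e_lo, e_hi))
}

#' Expected peptide ion abundance
#'
#' Expected abundance is concentration times efficiency times the instrument
#' response factor, truncated at the detector saturation ceiling:
#' `mu = min(c * e * kappa, sat)`.
#'
#' @param c_pep Peptide concentration matrix (peptides x samples).
#' @param efficiency Per-peptide efficiency vector.
#' @param kappa Instrument response factor.
#' @param sat Saturation ceiling (`Inf` for a purely linear response).
#' @return Expected abundance matrix, same shape as `c_pep`.
#' @export
expected_abundance <- function(c_pep, efficiency, kappa = 5, sat = Inf) {
  if (length(efficiency) != nrow(c_pep)) {
    abort("`efficiency` length must equal nrow(c_pep)")
  }
  check_scalar(kappa, "kappa", lower = 1e-12)
  check_scalar(sat, "sat", lower = 1e-12, allow_inf = TRUE)
  pmin(c_pep * efficiency * kappa, sat)
}

#' Add signal-dependent Gaussian noise
#'
#' Observed abundance is `v = max(0, mu + eps)` with
#' `eps ~ N(0, alpha * mu^2 + beta * mu)` — noise variance is quadratic in
#' the expected abundance. Entries with `mu = 0` stay exactly zero.
#'
#' @param mu Expected abundance matrix.
#' @param alpha,beta Noise coefficients (variance scale).
#' @param seed Integer seed.
#' @return Noisy abundance matrix, elementwise non-negative.
#' @export
add_noise <- function(mu, alpha = 0.03, beta = 3.6, seed = NULL) {
  check_scalar(alpha, "alpha", lower = 0)
  check_scalar(beta, "beta", lower = 0)
  if (any(mu < 0)) abort("`mu` must be non-negative")
  with_seed(seed, {
    v <- mu + rnorm(length(mu)) * sqrt(alpha * mu * mu + beta * mu)
    v[v < 0] <- 0
    v[mu == 0] <- 0
    dim(v) <- dim(mu)
    dimnames(v) <- dimnames(mu)
    v
  })
}
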