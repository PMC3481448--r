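# Ground-truth protein concentration model: Gamma control means, fold-changed
# markers, block-correlated multivariate Gaussian sample variation.

#' Draw control-class protein mean concentrations
#'
#' Control means are i.i.d. Gamma(t, theta) (shape/scale), spanning roughly
#' four orders of magnitude at the default (2, 1000). If
#' `marker_quantile_cap = q` is set, marker means are instead drawn from the
#' same Gamma truncated to its lower-q quantile, emulating a study where all
#' markers are low-abundance proteins.
#'
#' @param n_proteins Number of proteins.
#' @param t,theta Gamma shape and scale.
#' @param marker_idx Integer indices of marker proteins (used only with the
#'   quantile cap).
#' @param marker_quantile_cap Optional upper Gamma quantile for marker means.
#' @param seed Integer seed.
#' @return Numeric vector of means, length `n_proteins`.
#' @export
draw_control_means <- function(n_proteins, t = 2, theta = 1000,
                               marker_idx = integer(0),
                               marker_quantile_cap = NULL, seed = NULL) {
  check_count(n_proteins, "n_proteins", 1L)
  with_seed(seed, {
    eta <- rgamma(n_proteins, shape = t, scale = theta)
    if (!is.null(marker_quantile_cap) && length(marker_idx) > 0) {
      q <- check_scalar(marker_quantile_cap, "marker_quantile_cap",
                        lower = 1e-12, upper = 1)
      # inverse-CDF draw restricted to the lower-q tail
      u <- runif(length(marker_idx), 0, q)
      eta[marker_idx] <- qgamma(u, shape = t, scale = theta)
    }
    eta
  })
}

#' Draw per-protein fold changes
#'
#' Markers receive a fold magnitude `a ~ Unif(a_lo, a_hi)`; a fair coin
#' decides over-expression (fold `a`) versus under-expression (fold `1/a`).
#' Non-markers have fold 1.
#'
#' @param n_proteins Number of proteins.
#' @param marker_idx Integer indices of markers.
#' @param a_lo,a_hi Fold magnitude bounds (> 1).
#' @param seed Integer seed.
#' @return Numeric fold vector of length `n_proteins`.
#' @export
draw_fold_changes <- function(n_proteins, marker_idx, a_lo = 1.5, a_hi = 2,
                              seed = NULL) {
  check_count(n_proteins, "n_proteins", 1L)
  if (a_lo <= 1 || a_hi < a_lo) abort("need 1 < a_lo <= a_hi")
  if (length(marker_idx) > 0 &&
      (min(marker_idx) < 1 || max(marker_idx) > n_proteins)) {
    abort("`marker_idx` out of range")
  }
  with_seed(seed, {
    fold <- rep(1, n_proteins)
    if (length(marker_idx) > 0) {
      a <- runif(length(marker_idx), a_lo, a_hi)
      up <- runif(length(marker_idx)) < 0.5
      fold[marker_idx] <- ifelse(up, a, 1 / a)
    }
    fold
  })
}

#' Build the block-diagonal protein covariance matrix
#'
#' Per-protein standard deviation is `phi * eta` (phi is the coefficient of
#' variation); proteins are assigned to consecutive blocks of size `D` in row
#' order, with correlation `rho` inside a block and 0 across blocks. A
#' trailing block smaller than `D` is allowed.
#'
#' @param eta Control mean vector.
#' @param phi Coefficient of variation.
#' @param rho Within-block correlation.
#' @param D Block size.
#' @return A dense covariance matrix (use for inspection or small problems;
#'   [draw_samples()] exploits the block structure and never forms it).
#' @export
build_covariance <- function(eta, phi = 0.1, rho = 0.6, D = 2) {
  n <- length(eta)
  check_scalar(phi, "phi", lower = 1e-12)
  check_count(D, "D", 1L)
  if (D > 1 && (rho <= -1 / (D - 1) || rho >= 1)) {
    abort("`rho` must lie in (-1/(D-1), 1) for a positive-definite block")
  }
  sdv <- phi * eta
  blk <- rep(seq_len(ceiling(n / D)), each = D)[seq_len(n)]
  R <- (outer(blk, blk, "==")) * rho
  diag(R) <- 1
  outer(sdv, sdv) * R
}

#' Draw ground-truth concentration samples for two classes
#'
#' Class-0 samples are multivariate Gaussian with mean `eta` and the
#' block-diagonal covariance implied by (`phi`, `rho`, `D`); class-1 samples
#' have mean `eta * fold` and the same covariance. Sampling is performed
#' block-by-block through the block Cholesky factor, which is exact for the
#' block-diagonal structure and scales to tens of thousands of proteins.
#' Negative draws are clamped to zero (concentrations are non-negative).
#'
#' @param eta Control means.
#' @param fold Fold-change vector (same length).
#' @param M Samples per class.
#' @param phi,rho,D Covariance parameters as in [build_covariance()].
#' @param marker_idx Marker row indices (carried through to the result).
#' @param protein_ids Optional protein id vector (row names of the matrix).
#' @param seed Integer seed.
#' @return A `ground_truth_samples` object: list with `concentrations`
#'   (n_proteins x 2M matrix, class-0 columns first), `class_labels` (0/1),
#'   `eta`, `fold`, `marker_idx`, `protein_ids`, and `clamp_rate` (fraction
#'   of entries clamped at zero).
#' @export
draw_samples <- function(eta, fold, M, phi = 0.1, rho = 0.6, D = 2,
                         marker_idx = integer(0), protein_ids = NULL,
                         seed = NULL) {
  n <- length(eta)
  if (length(fold) != n) abort("`eta` and `fold` lengths differ")
  check_count(M, "M", 1L)
  if (D > 1 && (rho <= -1 / (D - 1) || rho >= 1)) {
    abort("`rho` must lie in (-1/(D-1), 1) for a positive-definite block")
  }
  if (is.null(protein_ids)) protein_ids <- sprintf("PRO%05d", seq_len(n))
  with_seed(seed, {
    n_blocks <- ceiling(n / D)
    L <- if (D > 1) {
      t(chol(matrix(rho, D, D) + diag(1 - rho, D)))
    } else {
      matrix(1, 1, 1)
    }
    n_cols <- 2L * M
    # standard normals for full blocks; the leading rows of each block have
    # exactly the marginal law of the trailing partial block
    Z <- matrix(rnorm(D * n_blocks * n_cols), nrow = D)
    W <- L %*% Z                      # D x (n_blocks * n_cols), correlated rows
    X <- matrix(0, nrow = n, ncol = n_cols)
    for (j in seq_len(n_cols)) {
      cols <- ((j - 1L) * n_blocks + 1L):(j * n_blocks)
      X[, j] <- as.vector(W[, cols])[seq_len(n)]
    }
    sdv <- phi * eta
    mean0 <- eta
    mean1 <- eta * fold
    conc <- X * sdv +
      cbind(matrix(mean0, n, M), matrix(mean1, n, M))
    clamp_rate <- mean(conc < 0)
    conc[conc < 0] <- 0
    rownames(conc) <- protein_ids
    colnames(conc) <- c(sprintf("C0_S%04d", seq_len(M)),
                        sprintf("C1_S%04d", seq_len(M)))
    structure(
      list(concentrations = conc,
           class_labels = rep(c(0L, 1L), each = M),
           eta = eta, fold = fold,
           marker_idx = as.integer(marker_idx),
           marker_ids = protein_ids[marker_idx],
           protein_ids = protein_ids,
           clamp_rate = clamp_rate),
      class = "ground_truth_samples"
    )
  })
}

#' @export
print.ground_truth_samples <- function(x, ...) {
  cat(sprintf(
    "<ground_truth_samples> %d proteins x %d samples (%d markers)\n",
    nrow(x$concentrations), ncol(x$concentrations), length(x$marker_idx)))
  invisible(x)
}

#' Simulate a full two-class ground truth from a configuration
#'
#' Composes [draw_control_means()], [draw_fold_changes()] and
#' [draw_samples()] under the configuration's parameters. Markers occupy the
#' first slot of each of the first `n_markers` correlation blocks, so each
#' marker's block partners are background proteins.
#'
#' @param config A [sim_config()].
#' @param protein_ids Protein ids, length `n_markers + n_background`; the
#'   first `n_markers` ids are treated as the markers before interleaving.
#' @param seed Integer run seed (stage seeds are derived from it).
#' @return A list with the `ground_truth_samples` for the training design and
#'   the marker interleaving order (`order`) applied to `protein_ids`.
#' @export
simulate_ground_truth <- function(config, protein_ids, seed = NULL) {
  stopifnot(inherits(config, "pipesim_config"))
  n <- config$n_markers + config$n_background
  if (length(protein_ids) != n) {
    abort("`protein_ids` must have length n_markers + n_background")
  }
  ord <- marker_interleave_order(config$n_markers, config$n_background,
                                 config$D)
  ids <- protein_ids[ord]
  marker_idx <- match(protein_ids[seq_len(config$n_markers)], ids)
  eta <- draw_control_means(
    n, t = config$t, theta = config$theta, marker_idx = marker_idx,
    marker_quantile_cap = config$marker_quantile_cap,
    seed = if (is.null(seed)) NULL else stage_seed(seed, "eta"))
  fold <- draw_fold_changes(
    n, marker_idx, a_lo = config$a_lo, a_hi = config$a_hi,
    seed = if (is.null(seed)) NULL else stage_seed(seed, "fold"))
  truth <- draw_samples(
    eta, fold, config$M, phi = config$phi, rho = config$rho, D = config$D,
    marker_idx = marker_idx, protein_ids = ids,
    seed = if (is.null(seed)) NULL else stage_seed(seed, "samples_train"))
  list(truth = truth, order = ord, eta = eta, fold = fold,
       marker_idx = marker_idx)
}

# Interleave markers so marker m sits at the first slot of block m.
marker_interleave_order <- function(n_markers, n_background, D) {
  n <- n_markers + n_background
  if (D <= 1 || n_markers == 0) return(seq_len(n))
  ord <- integer(0)
  bg <- n_markers + seq_len(n_background)
  used_bg <- 0L
  for (m in seq_len(n_markers)) {
    fill <- min(D - 1L, n_background - used_bg)
    ord <- c(ord, m, bg[used_bg + seq_len(fill)])
    used_bg <- used_bg + fill
  }
  rest <- if (used_bg < n_background) bg[(used_bg + 1L):n_background]
          else integer(0)
  c(ord, rest)
}
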