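# Peptide-to-protein abundance roll-up: three-stage filtering, averaging,
# quantification error and missing-value rates.

#' Filter observed peptides ahead of protein roll-up
#'
#' Three-stage filter: (1) only peptides unique to one protein are kept;
#' (2) peptides with missing-value rate above `max_missing_rate` are removed
#' (low reproducibility flags dubious identifications); (3) among each
#' protein's remaining peptides, a peptide survives only if its Pearson
#' correlation with at least one sibling peptide of the same protein exceeds
#' `min_corr`, computed over samples where both are observed (pairs with
#' fewer than 3 common samples contribute no qualifying correlation). A
#' protein left with a single peptide after stage 2 has no sibling, so that
#' peptide fails stage 3.
#'
#' @param table An `observed_peptide_table` from [link_observations()].
#' @param catalog The digested `proteome_catalog` the table was built from.
#' @param max_missing_rate,min_corr,unique_only Filter thresholds (see
#'   [sim_config()]).
#' @return A list with `survivors` (tibble: `peptide_idx`, `peptide_id`,
#'   `protein_id`) and `audit` (tibble: `peptide_id`, `removed_at`, one of
#'   `"unique"`, `"missing"`, `"correlation"`, or `NA` for survivors).
#' @export
filter_peptides <- function(table, catalog, max_missing_rate = 0.7,
                            min_corr = 0.6, unique_only = TRUE) {
  stopifnot(inherits(table, "observed_peptide_table"),
            inherits(catalog, "proteome_catalog"))
  n_pep <- catalog$n_pep
  if (nrow(table$observed) != n_pep) {
    abort("table and catalog disagree on the number of peptide species")
  }
  removed_at <- rep(NA_character_, n_pep)

  stage1 <- if (unique_only) catalog$peptides$is_unique else rep(TRUE, n_pep)
  removed_at[!stage1] <- "unique"

  miss_rate <- rowMeans(!table$observed)
  stage2 <- stage1 & miss_rate <= max_missing_rate
  removed_at[stage1 & !stage2] <- "missing"

  parent1 <- vapply(catalog$peptides$parents, `[`, character(1), 1L)
  keep <- logical(n_pep)
  idx_by_protein <- split(which(stage2), parent1[stage2])
  for (idx in idx_by_protein) {
    if (length(idx) < 2L) next
    A <- table$abundance[idx, , drop = FALSE]
    O <- !is.na(A)
    common <- tcrossprod(O * 1)                    # pairwise common samples
    cm <- suppressWarnings(cor(t(A), use = "pairwise.complete.obs"))
    qual <- !is.na(cm) & cm > min_corr & common >= 3
    diag(qual) <- FALSE
    keep[idx[rowSums(qual) > 0]] <- TRUE
  }
  removed_at[stage2 & !keep] <- "correlation"

  list(
    survivors = tibble::tibble(
      peptide_idx = which(keep),
      peptide_id = catalog$peptides$peptide_id[keep],
      protein_id = parent1[keep]
    ),
    audit = tibble::tibble(
      peptide_id = catalog$peptides$peptide_id,
      removed_at = removed_at
    )
  )
}

#' Roll surviving peptides up to protein estimates
#'
#' For proteins with at least `min_peptides` surviving peptides, the
#' estimated protein abundance in a sample is the mean of the survivors'
#' abundances observed in that sample (zero when none is observed there);
#' proteins with fewer survivors get an all-zero row. Estimated concentration
#' is estimated abundance divided by the instrument response factor.
#'
#' @param abundance NA-masked peptide abundance matrix (as in an
#'   `observed_peptide_table`); pass the training or an independently
#'   generated test matrix — the survivor set is reused unchanged.
#' @param survivors Survivor tibble from [filter_peptides()].
#' @param protein_ids Protein ids defining the output row order.
#' @param kappa Instrument response factor.
#' @param min_peptides Minimum surviving peptides for a protein to be
#'   quantified.
#' @return A `protein_estimate`: list with `abundance_hat`, `conc_hat`
#'   (proteins x samples), `quantified` (logical per protein), and
#'   `n_survivors` per protein.
#' @export
estimate_protein <- function(abundance, survivors, protein_ids, kappa = 5,
                             min_peptides = 2) {
  check_count(min_peptides, "min_peptides", 1L)
  n_pro <- length(protein_ids)
  n_s <- ncol(abundance)
  hat <- matrix(0, n_pro, n_s,
                dimnames = list(protein_ids, colnames(abundance)))
  n_surv <- table(factor(survivors$protein_id, levels = protein_ids))
  ok <- names(n_surv)[n_surv >= min_peptides]
  if (length(ok) > 0) {
    sv <- survivors[survivors$protein_id %in% ok, ]
    A <- abundance[sv$peptide_idx, , drop = FALSE]
    obs <- !is.na(A)
    A0 <- A
    A0[!obs] <- 0
    sums <- rowsum(A0, group = sv$protein_id)
    cnts <- rowsum(obs * 1, group = sv$protein_id)
    est <- sums / pmax(cnts, 1)
    est[cnts == 0] <- 0
    hat[rownames(est), ] <- est
  }
  structure(
    list(abundance_hat = hat, conc_hat = hat / kappa,
         quantified = rowSums(hat != 0) > 0,
         n_survivors = as.integer(n_surv)),
    class = "protein_estimate"
  )
}

#' @export
print.protein_estimate <- function(x, ...) {
  cat(sprintf(
    "<protein_estimate> %d proteins x %d samples; quantified: %d (%.1f%%)\n",
    nrow(x$abundance_hat), ncol(x$abundance_hat), sum(x$quantified),
    100 * mean(x$quantified)))
  invisible(x)
}

#' Mean relative quantification error
#'
#' Mean over all proteins and samples of `|c - c_hat| / c`, where `c` is the
#' true and `c_hat` the estimated concentration. Unquantified proteins
#' contribute error 1 per entry. Entries with true concentration zero are
#' excluded with a warning (the relative error is undefined there).
#'
#' @param truth A `ground_truth_samples` object (or a true concentration
#'   matrix).
#' @param estimate A `protein_estimate` (or an estimated concentration
#'   matrix), same protein/sample order.
#' @return A single non-negative number; 0 for perfect estimates, 1 when
#'   nothing is quantified.
#' @export
quantification_error <- function(truth, estimate) {
  c_true <- if (inherits(truth, "ground_truth_samples")) {
    truth$concentrations
  } else {
    truth
  }
  c_hat <- if (inherits(estimate, "protein_estimate")) {
    estimate$conc_hat
  } else {
    estimate
  }
  if (!identical(dim(c_true), dim(c_hat))) {
    abort("truth and estimate dimensions differ")
  }
  pos <- c_true > 0
  if (!all(pos)) {
    warn(sprintf("excluding %d entr%s with zero true concentration",
                 sum(!pos), if (sum(!pos) == 1) "y" else "ies"))
  }
  mean(abs(c_true[pos] - c_hat[pos]) / c_true[pos])
}

#' Peptide- and protein-level missing value rates
#'
#' @param table An `observed_peptide_table`.
#' @param estimate A `protein_estimate`.
#' @return A list: `peptide` = fraction of (peptide, sample) cells not
#'   observed; `protein` = fraction of (protein, sample) cells with zero
#'   estimated abundance.
#' @export
missing_value_rates <- function(table, estimate) {
  list(peptide = mean(!table$observed),
       protein = mean(estimate$abundance_hat == 0))
}
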