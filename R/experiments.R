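# End-to-end pipeline runs and configuration sweeps.

#' Run the full simulated pipeline once
#'
#' Composes every stage under one seed: subsample the proteome (markers +
#' background), draw ground-truth concentrations for the training design and
#' an independent test design, digest, map to peptide signals, add noise,
#' detect (MS1), identify (MS2), link, roll up to protein estimates, and
#' evaluate. The test samples are pushed through the same pipeline
#' realization (same efficiencies, identifiabilities and survivor sets, fresh
#' noise and detection draws), so the classifier feature spaces match between
#' training and test.
#'
#' @param config A [sim_config()].
#' @param seed Integer run seed; every stage derives its own stream from it,
#'   so the result is fully reproducible.
#' @param proteome A `proteome_catalog` (proteins only) to subsample from;
#'   when `NULL`, a synthetic proteome four times the needed size is
#'   generated under the run seed.
#' @return A `run_result`: list of performance indices (`peptide_id_rate`,
#'   `protein_quant_rate`, `peptide_missing_rate`, `protein_missing_rate`,
#'   `qerr`, `pct_markers_detected`, `err_knn_observed`, `err_lda_observed`,
#'   `err_knn_original`, `err_lda_original`) plus the seed and config.
#' @export
run_once <- function(config, seed, proteome = NULL) {
  stopifnot(inherits(config, "pipesim_config"))
  seed <- check_count(seed, "seed", 0L)
  n_sel <- config$n_markers + config$n_background
  if (is.null(proteome)) {
    proteome <- generate_synthetic_proteome(4L * n_sel,
                                            seed = stage_seed(seed,
                                                              "subsample"))
  }
  stopifnot(inherits(proteome, "proteome_catalog"))
  if (proteome$n_pro < n_sel) {
    abort("proteome smaller than n_markers + n_background")
  }

  # --- subsample proteome; the first n_markers sampled ids are the markers
  pick <- with_seed(stage_seed(seed, "subsample"),
                    sample.int(proteome$n_pro, n_sel))
  ids <- proteome$proteins$protein_id[pick]

  # --- ground truth (training design), markers interleaved into blocks
  gt <- simulate_ground_truth(config, ids, seed = seed)
  truth <- gt$truth

  # --- independent test design from the same abundance model
  truth_test <- draw_samples(
    gt$eta, gt$fold, config$n_test_per_class,
    phi = config$phi, rho = config$rho, D = config$D,
    marker_idx = gt$marker_idx, protein_ids = truth$protein_ids,
    seed = stage_seed(seed, "samples_test"))

  # --- digest the subsampled proteome in the truth's row order
  sub <- new_proteome_catalog(
    proteome$proteins[pick, ][gt$order, ])
  catalog <- digest(sub, missed_cleavages = config$missed_cleavages,
                    min_length = config$min_length,
                    max_length = config$max_length,
                    n_scans = config$n_scans)

  # --- peptide signal
  c_pep <- peptide_concentrations(catalog, truth)
  c_pep_test <- peptide_concentrations(catalog, truth_test)
  eff <- draw_efficiencies(catalog, e_lo = config$e_lo, e_hi = config$e_hi,
                           seed = stage_seed(seed, "efficiency"))
  mu <- expected_abundance(c_pep, eff, kappa = config$kappa, sat = config$sat)
  mu_test <- expected_abundance(c_pep_test, eff, kappa = config$kappa,
                                sat = config$sat)
  v <- add_noise(mu, config$alpha, config$beta,
                 seed = stage_seed(seed, "noise_train"))
  v_test <- add_noise(mu_test, config$alpha, config$beta,
                      seed = stage_seed(seed, "noise_test"))

  # --- detection + identification
  ov <- overlap_counts(catalog, mass_resolution = config$mass_resolution,
                       n_scans = config$n_scans,
                       rt_tol_frac = config$rt_tol_frac)
  tpr_m <- tpr(snr(mu, config$alpha, config$beta), overlap = ov,
               k = config$k, p = config$p, b = config$b,
               overlap_aware = config$overlap_aware,
               perfect_detection = config$perfect_detection)
  tpr_t <- tpr(snr(mu_test, config$alpha, config$beta), overlap = ov,
               k = config$k, p = config$p, b = config$b,
               overlap_aware = config$overlap_aware,
               perfect_detection = config$perfect_detection)
  det <- detect_ms1(tpr_m, seed = stage_seed(seed, "ms1_train"))
  det_test <- detect_ms1(tpr_t, seed = stage_seed(seed, "ms1_test"))
  p_i <- assign_identifiability(catalog, model = config$identifiability,
                                seed = stage_seed(seed, "identifiability"))
  idf <- identify_ms2(p_i, ncol(v), config$n_ms2_replicates,
                      seed = stage_seed(seed, "ms2_train"))
  idf_test <- identify_ms2(p_i, ncol(v_test), config$n_ms2_replicates,
                           seed = stage_seed(seed, "ms2_test"))
  table <- link_observations(det, idf, v, identifiability = p_i,
                             overlap = ov)
  table_test <- link_observations(det_test, idf_test, v_test,
                                  identifiability = p_i, overlap = ov)

  # --- roll-up (filters learned on training data, reused on test data)
  filt <- filter_peptides(table, catalog,
                          max_missing_rate = config$max_missing_rate,
                          min_corr = config$min_corr,
                          unique_only = config$unique_only)
  est <- estimate_protein(table$abundance, filt$survivors,
                          truth$protein_ids, kappa = config$kappa,
                          min_peptides = config$min_peptides)
  est_test <- estimate_protein(table_test$abundance, filt$survivors,
                               truth$protein_ids, kappa = config$kappa,
                               min_peptides = config$min_peptides)

  # --- evaluation
  labels <- truth$class_labels
  labels_test <- truth_test$class_labels
  mvr <- missing_value_rates(table, est)
  qerr <- quantification_error(truth, est)
  pct <- detect_markers(est, labels, gt$marker_idx,
                        alpha_level = config$alpha_level)

  cls_obs <- classify_block(est$conc_hat, labels, est_test$conc_hat,
                            labels_test, config)
  cls_ori <- classify_block(truth$concentrations, labels,
                            truth_test$concentrations, labels_test, config)

  structure(
    list(
      indices = c(
        peptide_id_rate = mean(rowSums(idf) > 0),
        protein_quant_rate = mean(est$quantified),
        peptide_missing_rate = mvr$peptide,
        protein_missing_rate = mvr$protein,
        qerr = qerr,
        pct_markers_detected = pct,
        err_knn_observed = cls_obs$err_knn,
        err_lda_observed = cls_obs$err_lda,
        err_knn_original = cls_ori$err_knn,
        err_lda_original = cls_ori$err_lda
      ),
      n_pep = catalog$n_pep,
      seed = seed,
      config = config
    ),
    class = "run_result"
  )
}

# Feature selection + both classifiers on one (train, test) pair. When
# nothing is quantified there is no feature space; report chance error.
classify_block <- function(x_train, labels, x_test, labels_test, config) {
  sel <- withCallingHandlers(
    select_features(x_train, labels, n_features = config$n_features),
    warning = function(w) invokeRestart("muffleWarning"))
  if (length(sel) == 0) return(list(err_knn = 0.5, err_lda = 0.5))
  train_and_test_classifiers(t(x_train[sel, , drop = FALSE]), labels,
                             t(x_test[sel, , drop = FALSE]), labels_test,
                             knn_k = config$knn_k)
}

#' @export
print.run_result <- function(x, ...) {
  cat("<run_result> seed", x$seed, "\n")
  print(round(x$indices, 4))
  invisible(x)
}

#' Sweep one configuration parameter over a grid
#'
#' Re-runs the pipeline `n_runs` times per grid value with seeds
#' `seed_base + run`, so runs with the same index are seed-paired across
#' grid values. The proteome is generated (or given) once and subsampled
#' afresh within each run.
#'
#' @param config Base [sim_config()].
#' @param param Name of the configuration field to sweep.
#' @param values Grid of values.
#' @param n_runs Replicate runs per value.
#' @param seed_base Base seed.
#' @param proteome Optional `proteome_catalog` to subsample from; generated
#'   synthetically when `NULL`.
#' @param modify Optional `function(args, value)` that edits the plain
#'   argument list of [sim_config()] for one grid value (used for coupled
#'   parameters, e.g. noise sweeps that set `beta = 120 * alpha`); when
#'   supplied, `param` only labels the output.
#' @return A `sweep_summary`: list with `results` (long tibble: one row per
#'   run x index) and `summary` (per value x index mean, median, sd).
#' @export
run_sweep <- function(config, param, values, n_runs = 50, seed_base = 1,
                      proteome = NULL, modify = NULL) {
  stopifnot(inherits(config, "pipesim_config"))
  check_count(n_runs, "n_runs", 1L)
  if (is.null(modify) && !param %in% names(config)) {
    abort(sprintf("unknown configuration parameter: %s", param))
  }
  if (is.null(proteome)) {
    n_sel <- config$n_markers + config$n_background
    proteome <- generate_synthetic_proteome(4L * n_sel, seed = seed_base)
  }
  rows <- list()
  for (vi in seq_along(values)) {
    args <- unclass(config)
    if (is.null(modify)) {
      args[[param]] <- values[[vi]]
    } else {
      args <- modify(args, values[[vi]])
    }
    cfg <- do.call(sim_config, args)
    for (r in seq_len(n_runs)) {
      res <- run_once(cfg, seed = seed_base + r, proteome = proteome)
      rows[[length(rows) + 1L]] <- tibble::tibble(
        param = param, value = values[[vi]], run = r, seed = seed_base + r,
        index = names(res$indices), score = unname(res$indices)
      )
    }
  }
  results <- dplyr::bind_rows(rows)
  summary <- results |>
    dplyr::group_by(.data$param, .data$value, .data$index) |>
    dplyr::summarise(mean = mean(.data$score),
                     median = median(.data$score),
                     sd = sd(.data$score), .groups = "drop")
  structure(list(results = results, summary = summary, n_runs = n_runs),
            class = "sweep_summary")
}

#' @export
print.sweep_summary <- function(x, ...) {
  cat(sprintf("<sweep_summary> %s over %d value(s), %d run(s) each\n",
              x$summary$param[1], length(unique(x$summary$value)), x$n_runs))
  print(x$summary, n = 20)
  invisible(x)
}

#' Median of each performance index across runs
#'
#' @param results A list of `run_result` objects, or the `results` tibble of
#'   a `sweep_summary`.
#' @return A one-row tibble of per-index medians.
#' @export
summarize_medians <- function(results) {
  if (inherits(results, "run_result")) results <- list(results)
  if (is.data.frame(results)) {
    wide <- results |>
      dplyr::group_by(.data$index) |>
      dplyr::summarise(median = median(.data$score), .groups = "drop")
    return(tidyr::pivot_wider(wide, names_from = "index",
                              values_from = "median"))
  }
  if (length(results) == 0) abort("no results to summarize")
  mat <- do.call(rbind, lapply(results, function(r) r$indices))
  tibble::as_tibble(as.list(apply(mat, 2, median)))
}
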