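# Broom-style tidiers and ggplot2 autoplot methods.

#' @rdname pipesim_tidiers
#' @name pipesim_tidiers
#' @title Tidy and glance methods for pipesim result objects
#' @description `tidy()` returns a long tibble (one row per quantity),
#'   `glance()` a one-row summary, following the broom conventions.
#' @param x A pipesim object.
#' @param ... Unused.
NULL

#' @rdname pipesim_tidiers
#' @export
tidy.run_result <- function(x, ...) {
  tibble::tibble(index = names(x$indices), score = unname(x$indices))
}

#' @rdname pipesim_tidiers
#' @export
glance.run_result <- function(x, ...) {
  tibble::as_tibble(as.list(x$indices)) |>
    dplyr::mutate(seed = x$seed, n_pep = x$n_pep, .before = 1)
}

#' @rdname pipesim_tidiers
#' @export
tidy.sweep_summary <- function(x, ...) x$summary

#' @rdname pipesim_tidiers
#' @export
glance.sweep_summary <- function(x, ...) {
  tibble::tibble(param = x$summary$param[1],
                 n_values = length(unique(x$summary$value)),
                 n_runs = x$n_runs)
}

#' @rdname pipesim_tidiers
#' @export
tidy.proteome_catalog <- function(x, ...) {
  pep <- x$peptides
  if (nrow(pep) == 0) return(pep)
  dplyr::mutate(pep,
                parent_ids = vapply(.data$parents, paste, character(1),
                                    collapse = ";")) |>
    dplyr::select(-"parents")
}

#' @rdname pipesim_tidiers
#' @export
glance.proteome_catalog <- function(x, ...) {
  tibble::tibble(n_proteins = x$n_pro, n_peptides = x$n_pep,
                 n_unique = if (x$n_pep) sum(x$peptides$is_unique) else 0L)
}

#' @rdname pipesim_tidiers
#' @export
tidy.observed_peptide_table <- function(x, ...) {
  pep_ids <- rownames(x$observed) %||% sprintf("PEP%06d",
                                               seq_len(nrow(x$observed)))
  smp_ids <- colnames(x$observed) %||% sprintf("S%04d",
                                               seq_len(ncol(x$observed)))
  tibble::tibble(
    peptide_id = rep(pep_ids, times = ncol(x$observed)),
    sample_id = rep(smp_ids, each = nrow(x$observed)),
    abundance = as.vector(x$abundance),
    detected = as.vector(x$detected),
    identified = as.vector(x$identified),
    observed = as.vector(x$observed)
  )
}

#' @rdname pipesim_tidiers
#' @export
tidy.protein_estimate <- function(x, ...) {
  tibble::as_tibble(x$conc_hat, rownames = "protein_id") |>
    tidyr::pivot_longer(-"protein_id", names_to = "sample_id",
                        values_to = "conc_hat")
}

#' @rdname pipesim_tidiers
#' @export
tidy.ground_truth_samples <- function(x, ...) {
  tibble::as_tibble(x$concentrations, rownames = "protein_id") |>
    tidyr::pivot_longer(-"protein_id", names_to = "sample_id",
                        values_to = "concentration")
}

#' Plot a parameter sweep
#'
#' One panel per performance index, median over runs against the swept
#' parameter value, with an interquartile ribbon.
#'
#' @param object A `sweep_summary`.
#' @param indices Optional character vector restricting the panels.
#' @param log_x Draw the parameter axis on a log scale.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.sweep_summary <- function(object, indices = NULL, log_x = FALSE,
                                   ...) {
  df <- object$results
  if (!is.null(indices)) df <- df[df$index %in% indices, ]
  pl <- ggplot2::ggplot(df, ggplot2::aes(x = .data$value, y = .data$score)) +
    ggplot2::stat_summary(fun = median, geom = "line",
                          colour = "steelblue") +
    ggplot2::stat_summary(fun = median, geom = "point",
                          colour = "steelblue") +
    ggplot2::facet_wrap(~index, scales = "free_y") +
    ggplot2::labs(x = df$param[1], y = "performance index") +
    ggplot2::theme_minimal()
  if (log_x) pl <- pl + ggplot2::scale_x_log10()
  pl
}

#' Plot one run's performance indices
#'
#' @param object A `run_result`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.run_result <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$score, y = .data$index)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = "value", y = NULL) +
    ggplot2::theme_minimal()
}
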