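# Deterministic miniature fixtures for hand-checkable tests.

#' A five-protein toy proteome with known tryptic products
#'
#' Designed so the digestion and roll-up rules can be verified by hand:
#' proteins TP1-TP3 each digest into three peptides unique to them; TP4 and
#' TP5 share the peptide `TINYHQK` (so it is non-unique) and each carries a
#' single unique peptide, exercising the "fewer than two surviving peptides
#' means unquantified" rule.
#'
#' @param ideal_only If `TRUE`, return a three-protein variant where every
#'   protein digests into exactly two peptides unique to it, as needed by
#'   noiseless end-to-end identities (averaging two identical peptide values
#'   reproduces the protein concentration exactly, bit for bit).
#' @return A `proteome_catalog` with proteins only.
#' @export
make_toy_proteome <- function(ideal_only = FALSE) {
  seqs <- if (ideal_only) {
    c(TP1 = "MAGELVKTESTPEPTIDER",
      TP2 = "SAMPLEIKWEIGHTEDK",
      TP3 = "GLYCINEKHISTAMINEK")
  } else {
    c(TP1 = "MAGELVKTESTPEPTIDERGLIMPSEK",
      TP2 = "SAMPLEIKWEIGHTEDKDYNAMITEK",
      TP3 = "GLYCINEKHISTAMINEKFILAMENTK",
      TP4 = "VINTAGEKTINYHQK",
      TP5 = "TINYHQKDEADLIFTK")
  }
  new_catalog_from_sequences(seqs)
}

#' Golden end-to-end run at toy scale
#'
#' Runs the full pipeline on a small fixed configuration (5 markers over 30
#' background proteins, 10 samples per class, 50 test samples per class) at
#' the given seed. Used for regression testing: any numeric change in any
#' stage changes the result, and a committed snapshot detects it.
#'
#' @param seed Integer seed.
#' @return A `run_result`.
#' @export
make_pipeline_golden <- function(seed = 42) {
  cfg <- sim_config(M = 10, n_markers = 5, n_background = 30,
                    n_features = 10, n_test_per_class = 50)
  run_once(cfg, seed = seed)
}
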