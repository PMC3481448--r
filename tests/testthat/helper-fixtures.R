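# Shared fixtures: hand-sized catalogs and configs used across test files.

# A catalog with fabricated peptide annotations (masses/RTs chosen by the
# test), bypassing digestion. Parents default to one protein per peptide.
fake_catalog <- function(mass, rt, parents = NULL) {
  n <- length(mass)
  if (is.null(parents)) parents <- as.list(sprintf("P%03d", seq_len(n)))
  proteins <- tibble::tibble(protein_id = unique(unlist(parents)),
                             sequence = "ACDEFGHIK")
  peptides <- tibble::tibble(
    peptide_id = sprintf("PEP%06d", seq_len(n)),
    sequence = strrep("A", 7 + (seq_len(n) %% 5)),
    length = nchar(sequence),
    mono_mass = mass,
    rt = rt,
    parents = parents,
    n_parents = lengths(parents),
    is_unique = lengths(parents) == 1L
  )
  pipesim:::new_proteome_catalog(proteins, peptides)
}

# An observed peptide table built directly from an abundance matrix and
# logical masks (defaults: everything detected and identified).
fake_table <- function(v, detected = NULL, identified = NULL) {
  if (is.null(detected)) detected <- array(TRUE, dim(v))
  if (is.null(identified)) identified <- array(TRUE, dim(v))
  link_observations(detected, identified, v)
}

# Small but complete configuration for fast end-to-end unit tests.
tiny_config <- function(...) {
  sim_config(M = 10, n_markers = 5, n_background = 30, n_features = 10,
             n_test_per_class = 50, ...)
}

# The reduced-scale study design used by the trend-reproduction tests.
reduced_config <- function(...) {
  sim_config(n_background = 100, n_markers = 20, ...)
}

expect_all_finite <- function(x) {
  expect_true(all(is.finite(x)))
}
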