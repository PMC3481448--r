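#' Monoisotopic peptide mass
#'
#' Mass of an unmodified peptide: sum of residue monoisotopic masses plus one
#' water.
#'
#' @param sequence Character vector of peptide sequences over the 20 canonical
#'   residues.
#' @return Numeric vector of masses in Da.
#' @examples
#' mono_mass("G")        # glycine residue + water = 75.03203
#' mono_mass("PEPTIDE")
#' @export
mono_mass <- function(sequence) {
  if (length(sequence) == 0L) return(numeric(0))
  if (any(is.na(sequence)) || any(!nzchar(sequence))) {
    abort("peptide sequences must be non-empty")
  }
  chars <- strsplit(sequence, "", fixed = TRUE)
  vapply(chars, function(cc) {
    m <- AA_MONO_MASS[cc]
    if (anyNA(m)) {
      abort(sprintf("non-canonical residue(s) in sequence: %s",
                    paste(unique(cc[is.na(m)]), collapse = ", ")))
    }
    sum(m) + WATER_MONO_MASS
  }, numeric(1))
}

# Mean Kyte-Doolittle hydropathy of each sequence (GRAVY score).
gravy_score <- function(sequence) {
  chars <- strsplit(sequence, "", fixed = TRUE)
  vapply(chars, function(cc) mean(AA_KYTE_DOOLITTLE[cc]), numeric(1))
}

#' Predict peptide retention time
#'
#' Deterministic retention-time stand-in: the mean Kyte-Doolittle hydropathy
#' of the peptide (its GRAVY score) is mapped through a logistic onto the scan
#' axis, so more hydrophobic peptides elute later. Only relative elution
#' proximity matters downstream (the signal-overlap rule), so any monotone
#' deterministic predictor is adequate.
#'
#' @param sequence Character vector of peptide sequences.
#' @param n_scans Number of LC scans.
#' @return Retention times in scan units, strictly inside (0, n_scans).
#' @examples
#' predict_rt(c("IIIIII", "DDDDDD"), n_scans = 1000)
#' @export
predict_rt <- function(sequence, n_scans = 1000) {
  check_count(n_scans, "n_scans", 1L)
  if (any(!nzchar(sequence))) abort("peptide sequences must be non-empty")
  n_scans * plogis(gravy_score(sequence))
}

new_proteome_catalog <- function(proteins, peptides = NULL) {
  if (is.null(peptides)) {
    peptides <- tibble::tibble(
      peptide_id = character(), sequence = character(),
      length = integer(), mono_mass = numeric(), rt = numeric(),
      parents = list(), n_parents = integer(), is_unique = logical()
    )
  }
  structure(
    list(proteins = proteins, peptides = peptides,
         n_pro = nrow(proteins), n_pep = nrow(peptides)),
    class = "proteome_catalog"
  )
}

#' @export
print.proteome_catalog <- function(x, ...) {
  cat(sprintf("<proteome_catalog> %d proteins, %d peptide species\n",
              x$n_pro, x$n_pep))
  if (x$n_pep > 0) {
    cat(sprintf("  unique peptides: %d (%.1f%%)\n", sum(x$peptides$is_unique),
                100 * mean(x$peptides$is_unique)))
  }
  invisible(x)
}

#' Read a protein FASTA file into a proteome catalog
#'
#' Accepts any standard FASTA (wrapped or single-line). Protein ids are taken
#' from the header up to the first whitespace; sequences are uppercased and
#' non-canonical residues (B, J, O, U, X, Z) are dropped with a warning.
#'
#' @param path Path to a FASTA file.
#' @return A `proteome_catalog` with proteins only (no peptides yet); pass it
#'   to [digest()] to populate peptides.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) abort(sprintf("FASTA file not found: %s", path))
  seqs <- tryCatch(Biostrings::readAAStringSet(path),
                   error = function(e) {
                     abort(sprintf("could not parse FASTA '%s': %s",
                                   path, conditionMessage(e)))
                   })
  if (length(seqs) == 0L) abort(sprintf("FASTA file has no records: %s", path))
  ids <- sub("\\s.*$", "", names(seqs))
  seq_chr <- toupper(as.character(seqs))
  cleaned <- gsub(sprintf("[^%s]", paste(AA_ALPHABET20, collapse = "")), "",
                  seq_chr)
  n_dropped <- sum(nchar(seq_chr) - nchar(cleaned))
  if (n_dropped > 0) {
    warn(sprintf("dropped %d non-canonical residue(s) while reading %s",
                 n_dropped, path))
  }
  if (any(!nzchar(cleaned))) abort("FASTA contains empty protein sequence(s)")
  new_proteome_catalog(tibble::tibble(protein_id = unname(ids),
                                      sequence = unname(cleaned)))
}

#' Generate a synthetic proteome
#'
#' Random protein sequences drawn i.i.d. over the 20 canonical residues at
#' Swiss-Prot background frequencies, with lengths from a normal law truncated
#' below at 50 residues. Serves as a download-free stand-in for a real
#' proteome FASTA.
#'
#' @param n_proteins Number of proteins.
#' @param length_mean,length_sd Mean and standard deviation of sequence
#'   length before truncation at 50.
#' @param seed Integer seed; same seed gives the identical proteome.
#' @return A `proteome_catalog` with proteins only.
#' @examples
#' prot <- generate_synthetic_proteome(10, seed = 1)
#' @export
generate_synthetic_proteome <- function(n_proteins, length_mean = 450,
                                        length_sd = 150, seed = NULL) {
  check_count(n_proteins, "n_proteins", 1L)
  with_seed(seed, {
    lens <- round(rnorm(n_proteins, length_mean, length_sd))
    bad <- which(lens < 50)
    while (length(bad) > 0) {
      lens[bad] <- round(rnorm(length(bad), length_mean, length_sd))
      bad <- bad[lens[bad] < 50]
    }
    residues <- sample(names(AA_SWISSPROT_FREQ), sum(lens), replace = TRUE,
                       prob = AA_SWISSPROT_FREQ)
    stops <- cumsum(lens)
    starts <- c(1, head(stops, -1) + 1)
    seqs <- vapply(seq_len(n_proteins), function(i) {
      paste(residues[starts[i]:stops[i]], collapse = "")
    }, character(1))
    new_proteome_catalog(tibble::tibble(
      protein_id = sprintf("SYN%05d", seq_len(n_proteins)),
      sequence = seqs
    ))
  })
}

# Tryptic fragments of one sequence: cleave C-terminal to K/R unless followed
# by P, allowing up to `mc` missed cleavage sites.
tryptic_fragments <- function(sequence, mc = 0) {
  cut_after <- gregexpr("(?<=[KR])(?!P)", sequence, perl = TRUE)[[1]]
  n <- nchar(sequence)
  bounds <- c(0L, setdiff(as.integer(cut_after) - 1L, c(-1L, n)), n)
  bounds <- sort(unique(bounds))
  n_piece <- length(bounds) - 1L
  out <- character(0)
  for (span in 0:mc) {
    i <- seq_len(n_piece - span)
    if (length(i) == 0) next
    out <- c(out, substring(sequence, bounds[i] + 1L, bounds[i + 1L + span]))
  }
  out
}

#' Digest a proteome catalog in silico
#'
#' Applies the trypsin rule (cleave C-terminal to K or R, except before P) to
#' every protein, keeps peptides within the length window, deduplicates
#' identical sequences across proteins (parent sets are merged, realizing the
#' peptide-to-protein membership map), and annotates each peptide species
#' with monoisotopic mass and predicted retention time.
#'
#' @param catalog A `proteome_catalog` with proteins.
#' @param missed_cleavages Maximum number of missed cleavage sites.
#' @param min_length,max_length Peptide length window (residues).
#' @param n_scans Number of LC scans used for retention-time prediction.
#' @return The catalog with its `peptides` tibble populated: columns
#'   `peptide_id`, `sequence`, `length`, `mono_mass`, `rt`, `parents`
#'   (list-column of protein ids), `n_parents`, `is_unique`.
#' @examples
#' cat6 <- new_catalog_from_sequences(c(P1 = "MAGELVKTESTPEPTIDER"))
#' digest(cat6, min_length = 1)$peptides$sequence
#' @export
digest <- function(catalog, missed_cleavages = 0, min_length = 6,
                   max_length = 40, n_scans = 1000) {
  stopifnot(inherits(catalog, "proteome_catalog"))
  if (catalog$n_pro == 0L) abort("catalog has no proteins to digest")
  check_count(missed_cleavages, "missed_cleavages", 0L)
  frag <- lapply(catalog$proteins$sequence, tryptic_fragments,
                 mc = missed_cleavages)
  df <- tibble::tibble(
    protein_id = rep(catalog$proteins$protein_id, lengths(frag)),
    sequence = unlist(frag)
  )
  df <- df[nchar(df$sequence) >= min_length &
             nchar(df$sequence) <= max_length, ]
  # one row per (protein, peptide sequence), then merge parents per sequence
  df <- dplyr::distinct(df, .data$protein_id, .data$sequence)
  pep <- df |>
    dplyr::group_by(.data$sequence) |>
    dplyr::summarise(parents = list(unique(.data$protein_id)),
                     .groups = "drop") |>
    dplyr::arrange(.data$sequence)
  pep <- tibble::tibble(
    peptide_id = sprintf("PEP%06d", seq_len(nrow(pep))),
    sequence = pep$sequence,
    length = nchar(pep$sequence),
    mono_mass = mono_mass(pep$sequence),
    rt = predict_rt(pep$sequence, n_scans = n_scans),
    parents = pep$parents,
    n_parents = lengths(pep$parents),
    is_unique = lengths(pep$parents) == 1L
  )
  out <- new_proteome_catalog(catalog$proteins, pep)
  attr(out, "n_scans") <- n_scans
  out
}

#' Build a catalog directly from named sequences
#'
#' Convenience constructor used by examples, fixtures and tests.
#'
#' @param sequences Named character vector (names become protein ids).
#' @return A `proteome_catalog` with proteins only.
#' @export
new_catalog_from_sequences <- function(sequences) {
  if (is.null(names(sequences)) || any(!nzchar(names(sequences)))) {
    abort("`sequences` must be a named character vector")
  }
  bad <- grepl(sprintf("[^%s]", paste(AA_ALPHABET20, collapse = "")),
               sequences)
  if (any(bad)) abort("sequences contain non-canonical residues")
  new_proteome_catalog(tibble::tibble(
    protein_id = names(sequences),
    sequence = unname(sequences)
  ))
}
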