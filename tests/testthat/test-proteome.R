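test_that("FASTA reading follows header and residue conventions", {
  path <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(
    ">P1 some description",
    "MKR",
    ">P2|sp another",
    "ACDEF",
    "GHIKL"
  ), path)
  cat <- read_fasta(path)
  expect_equal(cat$n_pro, 2L)
  expect_equal(cat$proteins$protein_id, c("P1", "P2|sp"))
  expect_equal(cat$proteins$sequence, c("MKR", "ACDEFGHIKL"))

  # non-canonical residues are dropped with a warning, case is normalized
  path2 <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">Q1 x", "mkXrUz"), path2)
  expect_warning(cat2 <- read_fasta(path2), "non-canonical")
  expect_equal(cat2$proteins$sequence, "MKR")

  # degenerate inputs
  path3 <- withr::local_tempfile(fileext = ".fasta")
  writeLines(character(0), path3)
  expect_error(read_fasta(path3), "no records|parse")
  expect_error(read_fasta(file.path(tempdir(), "nope.fasta")), "not found")
})

test_that("synthetic proteome generation is seeded and respects the length law", {
  a <- generate_synthetic_proteome(520, seed = 1)
  b <- generate_synthetic_proteome(520, seed = 1)
  c <- generate_synthetic_proteome(520, seed = 2)
  expect_equal(a$n_pro, 520L)
  expect_identical(a$proteins, b$proteins)
  expect_false(identical(a$proteins$sequence, c$proteins$sequence))
  expect_true(all(nchar(a$proteins$sequence) >= 50))
  expect_true(all(strsplit(paste(a$proteins$sequence[1:5], collapse = ""),
                           "")[[1]] %in% AA_ALPHABET20))

  one <- generate_synthetic_proteome(1, length_mean = 100, length_sd = 0,
                                     seed = 3)
  expect_equal(nchar(one$proteins$sequence), 100L)
})

test_that("tryptic digestion applies the K/R-not-before-P rule", {
  cat1 <- new_catalog_from_sequences(c(P1 = "MKRPAK"))
  dig <- digest(cat1, min_length = 1)
  expect_setequal(dig$peptides$sequence, c("MK", "RPAK"))

  # missed cleavage adds the spanning peptide
  dig1 <- digest(cat1, missed_cleavages = 1, min_length = 1)
  expect_setequal(dig1$peptides$sequence, c("MK", "RPAK", "MKRPAK"))

  # no K/R: the full sequence is the only peptide
  cat2 <- new_catalog_from_sequences(c(P1 = "AAAAAAA"))
  expect_equal(digest(cat2, min_length = 1)$peptides$sequence, "AAAAAAA")

  # length window filters
  dig6 <- digest(cat1, min_length = 6)
  expect_equal(dig6$n_pep, 0L)
})

test_that("toy proteome digests to the hand-enumerated peptide set", {
  dig <- digest(make_toy_proteome())
  expect_setequal(dig$peptides$sequence, c(
    "MAGELVK", "TESTPEPTIDER", "GLIMPSEK",
    "SAMPLEIK", "WEIGHTEDK", "DYNAMITEK",
    "GLYCINEK", "HISTAMINEK", "FILAMENTK",
    "VINTAGEK", "TINYHQK", "DEADLIFTK"
  ))
  shared <- dig$peptides[dig$peptides$sequence == "TINYHQK", ]
  expect_setequal(shared$parents[[1]], c("TP4", "TP5"))
  expect_false(shared$is_unique)
  expect_equal(sum(!dig$peptides$is_unique), 1L)
})

test_that("digestion invariants hold on a random proteome", {
  prot <- generate_synthetic_proteome(25, length_mean = 120, length_sd = 30,
                                      seed = 7)
  d1 <- digest(prot)
  d2 <- digest(prot)
  # idempotent / deterministic
  expect_identical(d1$peptides, d2$peptides)
  # peptide sequences unique within the catalog
  expect_equal(anyDuplicated(d1$peptides$sequence), 0L)
  # membership consistency: every peptide is a substring of all its parents
  seq_by_id <- setNames(prot$proteins$sequence, prot$proteins$protein_id)
  ok <- mapply(function(pep, parents) {
    all(vapply(parents, function(pr) grepl(pep, seq_by_id[[pr]], fixed = TRUE),
               logical(1)))
  }, d1$peptides$sequence, d1$peptides$parents)
  expect_true(all(ok))
  # uniqueness flag is exactly |parents| == 1
  expect_equal(d1$peptides$is_unique, d1$peptides$n_parents == 1L)
  # every protein with a cleavage site yields >= 2 peptides before filtering
  dall <- digest(prot, min_length = 1, max_length = 10000)
  per_protein <- table(unlist(dall$peptides$parents))
  has_site <- grepl("[KR](?!P)", substr(prot$proteins$sequence, 1,
                                        nchar(prot$proteins$sequence) - 1),
                    perl = TRUE)
  expect_true(all(per_protein[prot$proteins$protein_id[has_site]] >= 2))
})

test_that("monoisotopic mass is additive and matches reference values", {
  expect_equal(mono_mass("G"), 75.03203, tolerance = 1e-4)
  # concatenation adds residue masses and shares one water
  expect_equal(mono_mass("ACDEF"),
               mono_mass("AC") + mono_mass("DEF") - 18.0105646863,
               tolerance = 1e-9)
  expect_error(mono_mass(""), "non-empty")
  expect_error(mono_mass("ABZ"), "non-canonical")
})

test_that("retention-time prediction is deterministic, bounded, and hydrophobicity-ordered", {
  rt1 <- predict_rt("TESTPEPTIDEK", n_scans = 1000)
  rt2 <- predict_rt("TESTPEPTIDEK", n_scans = 1000)
  expect_identical(rt1, rt2)
  prot <- generate_synthetic_proteome(10, seed = 11)
  rts <- predict_rt(prot$proteins$sequence, n_scans = 1000)
  expect_true(all(rts > 0 & rts < 1000))
  # hydrophobic peptides elute later
  expect_gt(predict_rt("IIIIII", 1000), predict_rt("DDDDDD", 1000))
})
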