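test_that("the three roll-up filters remove the right peptides", {
  # catalog: pep1 shared (2 parents); pep2..pep4 unique to PA; pep5 unique to PB
  cat5 <- fake_catalog(
    mass = c(800, 900, 1000, 1100, 1200),
    rt = rep(500, 5),
    parents = list(c("PA", "PB"), "PA", "PA", "PA", "PB")
  )
  S <- 10
  base <- matrix(rep(seq_len(S) * 10, each = 5), 5, S, byrow = FALSE)
  det <- matrix(TRUE, 5, S)
  det[3, 1:8] <- FALSE      # pep3 observed in 2/10 samples: rate 0.8 > 0.7
  tab <- fake_table(base, detected = det)
  filt <- filter_peptides(tab, cat5)
  audit <- setNames(filt$audit$removed_at, filt$audit$peptide_id)
  expect_equal(unname(audit[1]), "unique")        # shared peptide
  expect_equal(unname(audit[3]), "missing")       # high missing rate
  # pep2 and pep4 are identical profiles: correlation 1, both kept
  expect_setequal(filt$survivors$peptide_idx, c(2L, 4L))
  # pep5 is PB's only remaining peptide: no sibling, fails stage 3
  expect_equal(unname(audit[5]), "correlation")
})

test_that("a lone sibling pair with too few common samples fails the correlation filter", {
  cat2 <- fake_catalog(mass = c(800, 900), rt = c(100, 200),
                       parents = list("PA", "PA"))
  v <- matrix(runif(2 * 10, 100, 200), 2, 10)
  det <- matrix(TRUE, 2, 10)
  det[1, 1:4] <- FALSE
  det[2, 5:10] <- FALSE      # no common observed sample at all
  filt <- filter_peptides(fake_table(v, detected = det), cat2,
                          max_missing_rate = 0.7)
  expect_equal(nrow(filt$survivors), 0L)
})

test_that("relaxing filter thresholds never shrinks the survivor set", {
  set.seed(31)
  n <- 40; S <- 20
  cat_r <- fake_catalog(mass = runif(n, 600, 4000), rt = runif(n, 0, 1000),
                        parents = as.list(rep(sprintf("PR%02d", 1:10), 4)))
  v <- matrix(rexp(n * S, 1 / 1000), n, S)
  det <- matrix(runif(n * S) < 0.7, n, S)
  tab <- fake_table(v, detected = det)
  strict <- filter_peptides(tab, cat_r, max_missing_rate = 0.4,
                            min_corr = 0.6)
  loose <- filter_peptides(tab, cat_r, max_missing_rate = 0.8,
                           min_corr = 0.2)
  expect_true(all(strict$survivors$peptide_idx %in%
                    loose$survivors$peptide_idx))
})

test_that("protein estimation averages survivors and divides by kappa", {
  surv <- tibble::tibble(peptide_idx = c(1L, 2L),
                         peptide_id = c("PEP000001", "PEP000002"),
                         protein_id = c("PA", "PA"))
  A <- matrix(c(10, 20, NA, 30), 2, 2)   # sample1: both; sample2: pep2 only
  est <- estimate_protein(A, surv, c("PA", "PB"), kappa = 5,
                          min_peptides = 2)
  expect_equal(est$abundance_hat["PA", ], c(15, 30), ignore_attr = TRUE)
  expect_equal(est$conc_hat["PA", ], c(3, 6), ignore_attr = TRUE)
  # PB has no survivors: all-zero row, unquantified
  expect_equal(unname(est$abundance_hat["PB", ]), c(0, 0))
  expect_equal(est$quantified, c(TRUE, FALSE), ignore_attr = TRUE)
  # a single surviving peptide is below min_peptides: protein set to zero
  est1 <- estimate_protein(A, surv[1, ], c("PA", "PB"), kappa = 5,
                           min_peptides = 2)
  expect_true(all(est1$abundance_hat == 0))
  # no survivor observed in a sample: zero there, protein still quantified
  A2 <- matrix(c(10, 20, NA, NA), 2, 2)
  est2 <- estimate_protein(A2, surv, c("PA", "PB"), kappa = 5)
  expect_equal(unname(est2$abundance_hat["PA", ]), c(15, 0))
  expect_true(est2$quantified["PA"])
})

test_that("quantification error behaves at its anchor points", {
  truth <- matrix(c(100, 200, 300, 400), 2, 2)
  expect_equal(quantification_error(truth, truth), 0)
  expect_equal(quantification_error(truth, truth * 0), 1)
  half <- truth; half[1, ] <- 0
  expect_equal(quantification_error(truth, half), 0.5)
  # zero true concentrations are excluded with a warning
  t0 <- truth; t0[1, 1] <- 0
  expect_warning(q <- quantification_error(t0, t0), "zero true")
  expect_equal(q, 0)
  expect_error(quantification_error(truth, truth[1, , drop = FALSE]),
               "dimensions")
})

test_that("missing value rates are computed at both levels", {
  v <- matrix(1, 4, 5)
  tab_all <- fake_table(v)
  surv <- tibble::tibble(peptide_idx = 1:2, peptide_id = c("x", "y"),
                         protein_id = c("PA", "PA"))
  est_all <- estimate_protein(v[1:2, ], surv, "PA", kappa = 1)
  expect_equal(missing_value_rates(tab_all, est_all),
               list(peptide = 0, protein = 0))
  tab_none <- fake_table(v, detected = matrix(FALSE, 4, 5))
  est_none <- estimate_protein(tab_none$abundance[1:2, ],
                               tibble::tibble(peptide_idx = integer(),
                                              peptide_id = character(),
                                              protein_id = character()),
                               "PA", kappa = 1)
  expect_equal(missing_value_rates(tab_none, est_none),
               list(peptide = 1, protein = 1))
})
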