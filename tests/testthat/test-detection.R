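test_that("SNR follows mu / (alpha mu + beta) with the right limits", {
  expect_equal(snr(matrix(0)), matrix(0))
  expect_equal(snr(matrix(120), 0.03, 3.6)[1], 120 / 7.2)
  expect_equal(snr(matrix(1e9), 0.03, 3.6)[1], 1 / 0.03, tolerance = 1e-4)
  # monotone non-decreasing in mu
  mu <- matrix(seq(0, 1e5, length.out = 100))
  expect_true(all(diff(snr(mu, 0.03, 3.6)) >= 0))
  # noiseless instrument: infinite SNR wherever there is signal
  s0 <- snr(matrix(c(0, 5)), 0, 0)
  expect_equal(s0[1], 0)
  expect_equal(s0[2], Inf)
})

test_that("overlap counting applies the joint mass/RT closeness rule", {
  # 5 ppm apart at resolving power 1e5 (tolerance 10 ppm), co-eluting
  cat1 <- fake_catalog(mass = c(1000, 1000.005), rt = c(500, 500))
  expect_equal(overlap_counts(cat1, mass_resolution = 1e5, n_scans = 1000,
                              rt_tol_frac = 0.005), c(2L, 2L))
  # same masses, far apart in RT: no overlap
  cat2 <- fake_catalog(mass = c(1000, 1000.005), rt = c(100, 900))
  expect_equal(overlap_counts(cat2, 1e5, 1000, 0.005), c(1L, 1L))
  # well separated masses never overlap
  cat3 <- fake_catalog(mass = c(1000, 1100), rt = c(500, 500))
  expect_equal(overlap_counts(cat3, 1e5, 1000, 0.005), c(1L, 1L))
  # an isolated peptide counts only itself
  expect_equal(overlap_counts(fake_catalog(1234.5, 200), 1e5), 1L)
  # three-way clash counts all members
  cat4 <- fake_catalog(mass = c(1000, 1000.001, 1000.002), rt = rep(300, 3))
  expect_equal(overlap_counts(cat4, 1e5, 1000, 0.005), c(3L, 3L, 3L))
})

test_that("the TPR curve is polynomial in SNR, clamped, and overlap-penalized", {
  expect_equal(tpr(matrix(25), k = 0.0016, p = 2, b = 0)[1], 1)  # clamped
  expect_equal(tpr(matrix(0), k = 0.0016, p = 2, b = 0)[1], 0)
  expect_equal(tpr(matrix(10), k = 0.0016, p = 2, b = 0)[1], 0.16)
  expect_equal(tpr(matrix(0), b = 0.05)[1], 0.05)                # TPR floor
  # overlap-sensitive algorithms divide by the clash size
  expect_equal(tpr(matrix(25), overlap = 4, overlap_aware = FALSE)[1], 0.25)
  expect_equal(tpr(matrix(25), overlap = 4, overlap_aware = TRUE)[1], 1)
  # perfect detection flag
  pd <- tpr(matrix(c(0, 1e-9, 50)), perfect_detection = TRUE)
  expect_equal(as.vector(pd), c(0, 1, 1))
  # infinite SNR saturates the curve
  expect_equal(tpr(matrix(Inf))[1], 1)
})

test_that("MS1 detection realizes the TPR as Bernoulli draws", {
  expect_true(all(detect_ms1(matrix(1, 10, 10), seed = 1)))
  expect_false(any(detect_ms1(matrix(0, 10, 10), seed = 1)))
  d <- detect_ms1(matrix(0.3, 1000, 100), seed = 2)
  expect_equal(mean(d), 0.3, tolerance = 0.01 / 0.3)
  expect_identical(d, detect_ms1(matrix(0.3, 1000, 100), seed = 2))
})

test_that("identifiability models give valid, seeded species-level probabilities", {
  cat_big <- fake_catalog(mass = runif(1e5, 600, 4000),
                          rt = runif(1e5, 0, 1000))
  p <- assign_identifiability(cat_big, seed = 1)
  expect_true(all(p >= 0 & p <= 1))
  expect_equal(mean(p), 0.2, tolerance = 0.005 / 0.2)
  expect_identical(p, assign_identifiability(cat_big, seed = 1))
  # deterministic alternative model needs no seed
  dig <- digest(make_toy_proteome())
  pl <- assign_identifiability(dig, model = list(model = "logistic"))
  expect_true(all(pl >= 0 & pl <= 1))
  expect_identical(pl, assign_identifiability(dig,
                                              model = list(model = "logistic")))
  expect_error(assign_identifiability(dig, model = list(model = "oracle")),
               "unknown")
})

test_that("MS2 identification follows the replicate success law", {
  p <- rep(0.5, 1000)
  id2 <- identify_ms2(p, n_samples = 100, n_replicates = 2, seed = 1)
  expect_equal(mean(id2), 0.75, tolerance = 0.01 / 0.75)
  expect_false(any(identify_ms2(rep(0, 100), 50, 3, seed = 2)))
  expect_true(all(identify_ms2(rep(1, 100), 50, 1, seed = 3)))
  # expected identified fraction is non-decreasing in the replicate count
  p_i <- draw_efficiencies(500, 0.05, 0.4, seed = 4)  # heterogeneous probs
  rates <- vapply(1:4, function(r) {
    mean(identify_ms2(p_i, 200, r, seed = 5))
  }, numeric(1))
  expect_true(all(diff(rates) > 0))
})

test_that("linking keeps only features reported by both algorithms", {
  v <- matrix(c(10, 20, 30, 40), 2, 2)
  det <- matrix(c(TRUE, TRUE, FALSE, FALSE), 2, 2)
  idf <- matrix(c(TRUE, FALSE, TRUE, FALSE), 2, 2)
  tab <- link_observations(det, idf, v)
  expect_equal(tab$observed, det & idf)
  expect_equal(tab$abundance[1, 1], 10)       # both fired
  expect_true(is.na(tab$abundance[2, 1]))     # detected only
  expect_true(is.na(tab$abundance[1, 2]))     # identified only
  expect_true(is.na(tab$abundance[2, 2]))     # neither
  expect_error(link_observations(det, idf[1, , drop = FALSE], v), "shape")
})

test_that("overlap-aware detection dominates overlap-sensitive detection", {
  cat4 <- fake_catalog(mass = rep(1000, 20) + seq(0, 19) * 1e-4,
                       rt = rep(500, 20))
  ov <- overlap_counts(cat4, mass_resolution = 1e4)
  snr_m <- matrix(20, 20, 200)
  det_aware <- detect_ms1(tpr(snr_m, ov, overlap_aware = TRUE), seed = 6)
  det_sens <- detect_ms1(tpr(snr_m, ov, overlap_aware = FALSE), seed = 6)
  expect_gte(sum(det_aware), sum(det_sens))
  expect_gt(sum(det_aware), 0)
})

test_that("empirical detection rates recover the TPR curve gain", {
  snr_vals <- c(5, 10, 15, 20)
  n <- 25000
  snr_m <- matrix(rep(snr_vals, each = n), nrow = n)
  det <- detect_ms1(tpr(snr_m, k = 0.0016, p = 2, b = 0), seed = 7)
  emp <- colMeans(det)
  fit <- lm(emp ~ 0 + I(snr_vals^2))
  expect_equal(unname(coef(fit)), 0.0016, tolerance = 0.1)
})
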