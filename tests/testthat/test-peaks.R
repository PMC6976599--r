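test_that("theoretical m/z follows the adduct arithmetic", {
  expect_equal(theoretical_mz(180, 1.00728, 1), 181.00728)
  expect_equal(theoretical_mz(180, -1.00728, 1), 178.99272)
  expect_equal(theoretical_mz(100, 1.00728, 2), 50.50364)
  expect_error(theoretical_mz(-5, 1.00728), "positive")
  expect_error(theoretical_mz(0.5, -1.00728), "nonpositive")
})

adducts_hp <- data.frame(
  name = c("[M+H]+", "[M-H]-"), mode = c("positive", "negative"),
  mass_shift = c(1.00728, -1.00728), charge = c(1L, 1L),
  stringsAsFactors = FALSE
)

test_that("peaks match within ppm tolerance and miss outside it", {
  db <- data.frame(met_id = "glc", monoisotopic_mass = 180,
                   name = "sugar", stringsAsFactors = FALSE)
  hit <- match_peaks(
    data.frame(peak_id = "p1", mz = 181.00728, mode = "positive"),
    db, adducts_hp, ppm_tol = 10
  )
  expect_equal(nrow(hit), 1L)
  expect_equal(hit$ppm_error, 0)
  expect_equal(hit$u, "p1")
  expect_equal(hit$v, "glc")

  # (181.01090 - 181.00728)/181.00728 * 1e6 = 20.0 ppm: outside tolerance
  miss <- match_peaks(
    data.frame(peak_id = "p1", mz = 181.01090, mode = "positive"),
    db, adducts_hp, ppm_tol = 10
  )
  expect_equal(nrow(miss), 0L)
})

test_that("ambiguous peaks keep every candidate metabolite", {
  db <- data.frame(met_id = c("m1", "m2"),
                   monoisotopic_mass = c(180, 180.0001),
                   name = c("a", "b"), stringsAsFactors = FALSE)
  hits <- match_peaks(
    data.frame(peak_id = "p1", mz = 181.00728, mode = "positive"),
    db, adducts_hp, ppm_tol = 10
  )
  expect_equal(nrow(hits), 2L)
  expect_setequal(hits$v, c("m1", "m2"))
})

test_that("matching configuration errors are explicit", {
  peaks <- data.frame(peak_id = "p1", mz = 181, mode = "positive")
  db <- data.frame(met_id = "m", monoisotopic_mass = 180, name = "x")
  expect_error(match_peaks(peaks, db, adducts_hp[0, ], 10), "empty")
  expect_error(match_peaks(peaks, db, adducts_hp, -1), "positive")
  neg_only <- adducts_hp[adducts_hp$mode == "negative", ]
  expect_error(match_peaks(peaks, db, neg_only, 10), "positive")
})

test_that("shrinking the tolerance never adds matches and errors re-check", {
  withr::with_seed(11, {
    db <- data.frame(met_id = sprintf("m%03d", 1:40),
                     monoisotopic_mass = runif(40, 100, 600),
                     name = "x", stringsAsFactors = FALSE)
    peaks <- data.frame(
      peak_id = sprintf("p%03d", 1:60),
      mz = (sample(db$monoisotopic_mass, 60, TRUE) + 1.00728) *
        (1 + rnorm(60, 0, 4) * 1e-6),
      mode = "positive", stringsAsFactors = FALSE
    )
  })
  tols <- c(20, 10, 5, 2, 1)
  counts <- integer(length(tols))
  for (i in seq_along(tols)) {
    m <- match_peaks(peaks, db, adducts_hp, ppm_tol = tols[i])
    counts[i] <- nrow(m)
    # every emitted edge re-checks within tolerance
    theo <- db$monoisotopic_mass[match(m$v, db$met_id)] + 1.00728
    obs <- peaks$mz[match(m$u, peaks$peak_id)]
    expect_true(all(abs(obs - theo) / theo * 1e6 <= tols[i] + 1e-9))
  }
  expect_true(all(diff(counts) <= 0))
})

test_that("noise-free synthetic peaks are all recovered at any tolerance", {
  bench <- peak_matching_benchmark(seed = 3, n_metabolites = 80,
                                   n_true = 50, decoy_count = 0,
                                   ppm_noise_sd = 0, ppm_tol = 0.5)
  expect_equal(bench$recall, 1)
})
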