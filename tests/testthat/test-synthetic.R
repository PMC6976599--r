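test_that("preferential attachment gives the expected size and is seeded", {
  ix <- generate_interactome(300, 2, seed = 8)
  expect_equal(nrow(ix$nodes), 300L)
  expect_equal(nrow(ix$edges), 596L)          # (n - m) * m
  expect_equal(igraph::components(as_igraph(ix))$no, 1L)
  ix2 <- generate_interactome(300, 2, seed = 8)
  expect_identical(ix, ix2)
  expect_false(identical(ix$edges$confidence,
                         generate_interactome(300, 2, seed = 9)$edges$confidence))
  allp <- generate_interactome(50, 2, kind_mix = c(protein = 1), seed = 1)
  expect_true(all(allp$nodes$kind == "protein"))
  expect_error(generate_interactome(2, 2), "attachment")
  # heavy tail: the busiest hub far exceeds the median degree
  expect_gte(max(node_degree(ix)), 5 * stats::median(node_degree(ix)))
})

test_that("planted modules are connected, disjoint and seeded", {
  ix <- generate_interactome(200, 2, seed = 3)
  truth <- plant_modules(ix, 2L, 12L, seed = 4)
  expect_equal(length(truth$module_assignments), 24L)
  expect_equal(anyDuplicated(names(truth$module_assignments)), 0L)
  g <- as_igraph(ix)
  for (mod in 1:2) {
    members <- names(truth$module_assignments)[truth$module_assignments == mod]
    sub <- igraph::induced_subgraph(g, members)
    expect_equal(igraph::components(sub)$no, 1L)
  }
  pair <- plant_modules(ix, 1L, 2L, seed = 5)
  members <- names(pair$module_assignments)
  expect_true(any(ix$edges$u %in% members & ix$edges$v %in% members))
  none <- plant_modules(ix, 0L, 5L, seed = 6)
  expect_equal(length(none$module_assignments), 0L)
  expect_identical(plant_modules(ix, 2L, 12L, seed = 4), truth)
})

test_that("omics generation separates planted signal from nulls", {
  ix <- generate_interactome(150, 2, seed = 10)
  truth <- plant_modules(ix, 1L, 10L, seed = 11)
  pure <- generate_omics(truth, ix, n_null = 0L, seed = 12)
  expect_equal(sort(pure$feature_id), sort(names(truth$module_assignments)))
  expect_true(all(pure$p_raw <= 1e-3))

  fixed <- generate_omics(truth, ix, effect_mu = 2, effect_sd = 0,
                          n_null = 0L, seed = 12)
  expect_equal(abs(fixed$log2fc), rep(2, 10))

  both <- generate_omics(truth, ix, n_null = 50L, seed = 13)
  expect_equal(nrow(both), 60L)
  expect_identical(both, generate_omics(truth, ix, n_null = 50L, seed = 13))
  # null_fraction controls how many nulls are mappable interactome nodes
  half <- generate_omics(truth, ix, n_null = 40L, null_fraction = 0.5,
                         seed = 14)
  nulls <- setdiff(half$feature_id, names(truth$module_assignments))
  expect_equal(sum(grepl("^null_", nulls)), 20L)
  expect_true(all(setdiff(nulls, grep("^null_", nulls, value = TRUE)) %in%
                    ix$nodes$id))
})

test_that("BH keeps null false positives near the nominal rate", {
  # binomial bound: over 40 seeds x 80 uniform nulls, the count of
  # BH-significant nulls stays within 3 sd of the alpha * n bound
  n_null <- 80L
  n_seeds <- 40L
  total_fp <- 0L
  ix <- generate_interactome(120, 2, seed = 20)
  truth <- plant_modules(ix, 0L, 2L, seed = 21)
  for (s in seq_len(n_seeds)) {
    om <- generate_omics(truth, ix, n_null = n_null, seed = 100 + s)
    adj <- adjust_differential(om)
    total_fp <- total_fp + sum(adj$p_adj < 0.05)
  }
  bound <- 0.05 * n_null * n_seeds
  expect_lte(total_fp, bound + 3 * sqrt(bound * 0.95))
})

test_that("generated peaks carry their planted identity", {
  ix <- generate_interactome(150, 2,
                             kind_mix = c(protein = 0.5, metabolite = 0.5),
                             seed = 30)
  truth <- plant_modules(ix, 1L, 12L, seed = 31)
  db <- generate_metabolite_db(ix, seed = 32)
  pk0 <- generate_peaks(truth, db, ppm_noise_sd = 0, seed = 33)
  n_planted_mets <- sum(names(truth$module_assignments) %in% db$met_id)
  expect_equal(nrow(pk0$peaks), n_planted_mets)
  if (n_planted_mets > 0) {
    m <- match_peaks(pk0$peaks, db, ppm_tol = 1)
    found <- paste(m$u, m$v)
    want <- paste(names(pk0$truth$true_peak_matches),
                  pk0$truth$true_peak_matches)
    expect_true(all(want %in% found))   # zero-noise recall is total
  }
  pk1 <- generate_peaks(truth, db, ppm_noise_sd = 2, decoy_count = 10L,
                        seed = 34)
  expect_identical(pk1,
                   generate_peaks(truth, db, ppm_noise_sd = 2,
                                  decoy_count = 10L, seed = 34))
  decoys <- grep("^decoy_", pk1$peaks$peak_id, value = TRUE)
  expect_length(decoys, 10L)
  m1 <- match_peaks(pk1$peaks, db, ppm_tol = 10)
  expect_false(any(m1$u %in% decoys))   # decoys sit >= 50 ppm away
})

test_that("a written dataset re-reads value-identically", {
  dir <- tempfile()
  ds <- write_synthetic_dataset(dir, n_nodes = 80, module_size = 6,
                                n_null = 20, decoy_count = 5, seed = 2)
  expect_true(all(file.exists(unlist(ds$paths))))
  om <- read.delim(ds$paths$differential, stringsAsFactors = FALSE)
  expect_equal(om$feature_id, ds$omics$feature_id)
  expect_equal(om$log2fc, ds$omics$log2fc, tolerance = 1e-12)
  pk <- read.delim(ds$paths$peaks, stringsAsFactors = FALSE)
  expect_equal(pk$mz, ds$peaks$mz, tolerance = 1e-12)
  edges <- read.delim(ds$paths$edges, stringsAsFactors = FALSE)
  expect_equal(nrow(edges), nrow(ds$interactome$edges))
  gmt <- read_gmt(ds$paths$gmt)
  expect_equal(gmt[[1]]$members,
               sort(names(ds$truth$module_assignments)))
})
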