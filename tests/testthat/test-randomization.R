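test_that("cost perturbation is seeded, clamped and degenerate at sigma 0", {
  ix <- generate_interactome(60, 2, seed = 5)
  expect_identical(perturb_costs(ix, sigma = 0, seed = 1), ix)
  p1 <- perturb_costs(ix, sigma = 0.1, seed = 1)
  p1b <- perturb_costs(ix, sigma = 0.1, seed = 1)
  p2 <- perturb_costs(ix, sigma = 0.1, seed = 2)
  expect_identical(p1$edges$cost, p1b$edges$cost)
  expect_true(any(p1$edges$cost != p2$edges$cost))
  big <- perturb_costs(ix, sigma = 5, seed = 3)
  expect_true(all(big$edges$cost >= 1e-6))
})

test_that("random prize placement preserves the prize multiset deterministically", {
  ix <- generate_interactome(100, 2, seed = 9)
  pt <- make_prizes(ix$nodes$id[c(3, 10, 25, 60)], c(2, 1.5, 0.7, 3))
  r1 <- random_prizes(pt, ix, seed = 4)
  r2 <- random_prizes(pt, ix, seed = 4)
  r3 <- random_prizes(pt, ix, seed = 5)
  expect_identical(r1, r2)
  expect_equal(sort(r1$prize), sort(pt$prize))
  expect_equal(nrow(r1), nrow(pt))
  expect_false(anyDuplicated(r1$node_id) > 0)
  expect_false(identical(r1$node_id, r3$node_id))
  expect_true(all(r1$node_id %in% ix$nodes$id))

  # a regular graph has a single degree bin: placement is unrestricted
  ring <- make_interactome(sprintf("r%02d", 1:8),
                           sprintf("r%02d", c(2:8, 1)), rep(0.2, 8))
  rr <- random_prizes(make_prizes(c("r01", "r02"), c(1, 2)), ring, seed = 1)
  expect_equal(nrow(rr), 2L)
  expect_error(random_prizes(make_prizes(paste0("x", 1:5), 1:5), ring),
               "not an interactome node")
})

test_that("node scores equal naive membership frequencies", {
  noisy <- list(c("a", "b"), c("a"), c("a", "c"), c("b", "c"))
  rand <- list(c("a"), c("d"), character(0), c("a", "d"))
  sc <- score_nodes(noisy, rand, extra_nodes = "e")
  expect_setequal(sc$node_id, c("a", "b", "c", "d", "e"))
  for (id in sc$node_id) {
    expect_equal(sc$robustness[sc$node_id == id],
                 oracle_frequency(noisy, id))
    expect_equal(sc$specificity[sc$node_id == id],
                 1 - oracle_frequency(rand, id))
  }
  expect_equal(sc$robustness[sc$node_id == "e"], 0)
  expect_error(score_nodes(list(), rand), "nonempty")
})

test_that("filtering is inclusive at the 40% boundary and needs both scores", {
  base <- new_forest(c("a", "b", "c"),
                     data.frame(u = c("a", "b"), v = c("b", "c"),
                                stringsAsFactors = FALSE), 1L)
  scores <- data.frame(
    node_id = c("a", "b", "c"),
    robustness = c(0.40, 0.39, 1.0),
    specificity = c(0.40, 0.95, 1.0),
    n_runs = 100
  )
  filt <- filter_nodes(base, scores, 0.40, 0.40)
  expect_setequal(filt$nodes, c("a", "c"))       # 0.40/0.40 kept, 0.39 dropped
  expect_equal(nrow(filt$edges), 0L)             # connecting node b is gone
  expect_equal(filt$n_trees, 2L)                 # forest split is recounted

  intact <- filter_nodes(base, scores, 0, 0)
  expect_setequal(intact$nodes, base$nodes)
  expect_equal(nrow(intact$edges), nrow(base$edges))

  expect_error(filter_nodes(base, scores[-1, ], 0.4, 0.4), "no .*score")
})

test_that("the filtered set shrinks monotonically in either threshold", {
  ix <- generate_interactome(80, 2, seed = 13)
  truth <- plant_modules(ix, 1L, 8L, seed = 14)
  pt <- make_prizes(names(truth$module_assignments),
                    rep(2, length(truth$module_assignments)))
  rr <- suppressMessages(
    run_randomization(ix, pt, pcsf_config(), n_runs = 15, seed = 3)
  )
  sizes <- vapply(c(0, 0.2, 0.4, 0.6, 0.8, 1.0), function(th) {
    length(filter_nodes(rr$base, rr$scores, th, 0)$nodes)
  }, 1L)
  expect_true(all(diff(sizes) <= 0))
  sizes2 <- vapply(c(0, 0.2, 0.4, 0.6, 0.8, 1.0), function(th) {
    length(filter_nodes(rr$base, rr$scores, 0, th)$nodes)
  }, 1L)
  expect_true(all(diff(sizes2) <= 0))
})
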