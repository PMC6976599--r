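# Shared 2-node instance: prizes A=5, B=3; one edge of cost 1.
two_node <- function() {
  list(ix = make_interactome("A", "B", 1),
       pt = make_prizes(c("A", "B"), c(5, 3)),
       cfg = pcsf_config(beta = 1, omega = 0.5, mu = 0))
}

test_that("the objective evaluates forfeits, edges, trees and hubs", {
  inst <- two_node()
  both <- new_forest(c("A", "B"),
                     data.frame(u = "A", v = "B", stringsAsFactors = FALSE),
                     1L)
  expect_equal(pcsf_objective(both, inst$ix, inst$pt, inst$cfg), 1.5)
  empty <- new_forest(character(),
                      data.frame(u = character(), v = character()), 0L)
  expect_equal(pcsf_objective(empty, inst$ix, inst$pt, inst$cfg), 8)
  only_a <- new_forest("A", data.frame(u = character(), v = character()), 1L)
  expect_equal(pcsf_objective(only_a, inst$ix, inst$pt, inst$cfg), 3.5)
  # hub penalty: both endpoints have interactome degree 1
  cfg_mu <- pcsf_config(beta = 1, omega = 0.5, mu = 0.1)
  expect_equal(pcsf_objective(both, inst$ix, inst$pt, cfg_mu), 1.5 + 0.2)
})

test_that("structurally invalid forests are rejected", {
  ix <- make_interactome(c("A", "B", "C"), c("B", "C", "A"),
                         c(0.2, 0.2, 0.2))
  pt <- make_prizes("A", 1)
  cfg <- pcsf_config()
  cyc <- new_forest(c("A", "B", "C"),
                    data.frame(u = c("A", "B", "A"), v = c("B", "C", "C")),
                    1L)
  expect_error(pcsf_objective(cyc, ix, pt, cfg), "cycle")
  foreign <- new_forest(c("A", "B"), data.frame(u = "A", v = "Z"), 1L)
  expect_error(pcsf_objective(foreign, ix, pt, cfg), "endpoint|foreign")
})

test_that("exhaustive enumeration finds the global optimum on the 2-node instance", {
  inst <- two_node()
  # by hand over all five candidate forests: {} = 8, {A} = 3.5, {B} = 5.5,
  # {A,B} with no edge = 0.5*2 = 1.0, {A,B,(A,B)} = 1.5 -> optimum 1.0
  bf <- brute_force_pcsf(inst$ix, inst$pt, inst$cfg)
  expect_setequal(bf$nodes, c("A", "B"))
  expect_equal(nrow(bf$edges), 0L)
  expect_equal(bf$n_trees, 2L)
  expect_equal(bf$objective, 1.0)

  # with a per-tree penalty above the edge cost the edge is taken
  cfg2 <- pcsf_config(beta = 1, omega = 2, mu = 0)
  bf2 <- brute_force_pcsf(inst$ix, inst$pt, cfg2)
  expect_equal(nrow(bf2$edges), 1L)
  expect_equal(bf2$objective, 1 + 2)

  # all prizes zero: nothing to collect
  zero <- brute_force_pcsf(inst$ix, make_prizes(c("A", "B"), c(0, 0)),
                           inst$cfg)
  expect_equal(length(zero$nodes), 0L)
  expect_equal(zero$objective, 0)

  # beta -> 0: prizes negligible against any cost
  tiny <- brute_force_pcsf(inst$ix, inst$pt, pcsf_config(beta = 1e-9))
  expect_equal(length(tiny$nodes), 0L)

  expect_error(
    brute_force_pcsf(generate_interactome(20, 2, seed = 1),
                     make_prizes("n01", 1), pcsf_config()),
    "cap"
  )
})

test_that("the heuristic matches the oracle on the worked examples", {
  inst <- two_node()
  heur <- solve_pcsf(inst$ix, inst$pt, inst$cfg)
  expect_equal(heur$objective, 1.0)

  # prized node whose only attachment is too expensive and whose prize is
  # below the tree-opening penalty is excluded
  ix <- make_interactome(c("A", "B"), c("B", "C"), c(0.1, 0.8))
  pt <- make_prizes(c("A", "C"), c(3, 0.5))
  cfg <- pcsf_config(beta = 1, omega = 1, mu = 0)
  heur2 <- solve_pcsf(ix, pt, cfg)
  bf2 <- brute_force_pcsf(ix, pt, cfg)
  expect_equal(heur2$objective, bf2$objective)
  expect_false("C" %in% heur2$nodes)

  # 5-node star with a crushing hub penalty: hub excluded, leaf prizes
  # forfeited (leaf degree-1 penalties also exceed their prizes here)
  star <- make_interactome(rep("hub", 4), paste0("L", 1:4), rep(0.1, 4))
  ptl <- make_prizes(paste0("L", 1:4), rep(1, 4))
  cfg_hub <- pcsf_config(beta = 1, omega = 1, mu = 10)
  h3 <- solve_pcsf(star, ptl, cfg_hub)
  b3 <- brute_force_pcsf(star, ptl, cfg_hub)
  expect_equal(h3$objective, b3$objective)
  expect_false("hub" %in% h3$nodes)
})

test_that("empty and unmapped prize tables are handled gracefully", {
  ix <- make_interactome("A", "B", 0.2)
  expect_warning(fo <- solve_pcsf(ix, make_prizes(character(), numeric())),
                 "empty")
  expect_equal(length(fo$nodes), 0L)
  expect_message(solve_pcsf(ix, make_prizes(c("A", "ZZZ"), c(1, 5))),
                 "absent")
})

test_that("every returned forest passes the structural audit", {
  cfg <- pcsf_config()
  for (s in 1:25) {
    inst <- random_small_instance(sample(4:9, 1), seed = 900 + s)
    fo <- solve_pcsf(inst$interactome, inst$prizes, cfg)
    kappa <- moanet:::validate_forest(fo, inst$interactome)  # errors if invalid
    expect_equal(kappa, fo$n_trees)
    expect_lte(fo$objective, cfg$beta * sum(inst$prizes$prize) + 1e-9)
  }
})

test_that("solves are deterministic and serialize byte-identically", {
  inst <- random_small_instance(9, seed = 77)
  f1 <- solve_pcsf(inst$interactome, inst$prizes, pcsf_config())
  f2 <- solve_pcsf(inst$interactome, inst$prizes, pcsf_config())
  expect_identical(f1, f2)
  d1 <- tempfile(); d2 <- tempfile()
  write_forest(f1, inst$interactome, inst$prizes, d1)
  write_forest(f2, inst$interactome, inst$prizes, d2)
  for (f in c("solution_nodes.tsv", "solution_edges.tsv", "solution.graphml")) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)))
  }
})
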