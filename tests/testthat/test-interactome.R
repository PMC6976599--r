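test_that("edge tables parse, drop self loops and reject bad confidences", {
  tab <- data.frame(source = c("A", "B", "C"), target = c("B", "C", "A"),
                    confidence = c(0.9, 0.8, 0.7))
  edges <- load_edge_table(write_edge_tsv(tab), "protein", "protein", "ppi")
  expect_equal(nrow(edges), 3L)
  expect_equal(edges$layer, rep("ppi", 3))
  expect_equal(edges$cost, 1 - tab$confidence)

  with_loop <- rbind(tab, data.frame(source = "D", target = "D",
                                     confidence = 0.5))
  expect_message(
    edges2 <- load_edge_table(write_edge_tsv(with_loop), "protein",
                              "protein", "ppi"),
    "self-loop"
  )
  expect_equal(nrow(edges2), 3L)

  bad <- data.frame(source = c("A", "B"), target = c("B", "C"),
                    confidence = c(0.5, 1.2))
  expect_error(
    load_edge_table(write_edge_tsv(bad), "protein", "protein", "ppi"),
    "row 2"
  )
  nocol <- data.frame(source = "A", target = "B", weight = 0.5)
  expect_error(
    load_edge_table(write_edge_tsv(nocol), "protein", "protein", "ppi"),
    "confidence"
  )
})

test_that("confidence-to-cost mapping is clamped, monotone and validated", {
  expect_equal(confidence_to_cost(0.9, 1e-6), 0.1)
  expect_equal(confidence_to_cost(1.0, 1e-6), 1e-6)
  expect_equal(confidence_to_cost(0.0), 1.0)
  conf <- seq(0, 1, by = 0.05)
  expect_true(all(diff(confidence_to_cost(conf)) <= 0))
  expect_true(all(confidence_to_cost(conf) > 0))
  expect_error(confidence_to_cost(1.5), "\\[0, 1\\]")
  expect_error(confidence_to_cost(0.5, epsilon = 0), "positive")
})

test_that("composition unions layers, keeps min cost and reconciles kinds", {
  l1 <- make_edges(c("A", "C"), c("B", "D"), c(0.2, 0.3), layer = "one")
  l2 <- make_edges(c("B", "E", "F"), c("A", "F", "G"), c(0.5, 0.1, 0.4),
                   layer = "two")
  ix <- compose_interactome(list(l1, l2))
  # duplicate (A,B) collapsed to min cost 0.2; 4 unique edges remain
  expect_equal(nrow(ix$edges), 4L)
  ab <- ix$edges[ix$edges$u == "A" & ix$edges$v == "B", ]
  expect_equal(ab$cost, 0.2)
  expect_setequal(ix$layer_manifest$layer, c("one", "two"))
  expect_equal(sum(ix$layer_manifest$n_edges), 5L)

  # disjoint layers simply union
  d1 <- make_edges(c("A", "B"), c("B", "C"), c(0.1, 0.2))
  d2 <- make_edges(c("X", "Y", "Z"), c("Y", "Z", "W"), c(0.1, 0.2, 0.3))
  expect_equal(nrow(compose_interactome(list(d1, d2))$edges), 5L)

  # kind conflicts are fatal and name the id
  k1 <- make_edges("X", "B", 0.2, kind_u = "protein")
  k2 <- make_edges("X", "C", 0.2, kind_u = "metabolite")
  expect_error(compose_interactome(list(k1, k2)), "X")
})

test_that("composition is idempotent and bounded by layer sums", {
  l1 <- make_edges(c("A", "B", "A"), c("B", "C", "C"), c(0.2, 0.3, 0.4))
  l2 <- make_edges(c("C", "A"), c("B", "B"), c(0.25, 0.1), layer = "l2")
  ix <- compose_interactome(list(l1, l2))
  again <- compose_interactome(list(interactome_edgelist(ix)))
  expect_equal(again$nodes, ix$nodes)
  expect_equal(again$edges[, c("u", "v", "cost")],
               ix$edges[, c("u", "v", "cost")])
  expect_lte(nrow(ix$edges), nrow(l1) + nrow(l2))
  expect_true(all(ix$edges$cost > 0))
})

test_that("interactome serialization round-trips through TSV and GraphML", {
  ix <- make_interactome(c("A", "B", "C"), c("B", "C", "D"),
                         c(0.2, 0.3, 0.4))
  dir <- tempfile()
  paths <- write_interactome(ix, dir)
  expect_true(all(file.exists(paths)))
  nodes <- read.delim(file.path(dir, "nodes.tsv"), stringsAsFactors = FALSE)
  edges <- read.delim(file.path(dir, "edges.tsv"), stringsAsFactors = FALSE)
  expect_equal(nodes$id, ix$nodes$id)
  expect_equal(edges$cost, ix$edges$cost)
  g <- igraph::read_graph(file.path(dir, "interactome.graphml"),
                          format = "graphml")
  expect_equal(igraph::vcount(g), nrow(ix$nodes))
  expect_equal(igraph::ecount(g), nrow(ix$edges))
})
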