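#' PCSF solver configuration
#'
#' The Prize-Collecting Steiner Forest objective minimized over forests
#' `F` of the interactome is
#'
#' \deqn{Obj(F) = \beta \sum_{v \notin F} p(v) + \sum_{e \in F} c(e) +
#'   \omega \kappa(F) + \mu \sum_{v \in F} deg(v)}
#'
#' where `p(v)` are node prizes, `c(e)` edge costs, `kappa(F)` the number
#' of trees and `deg` the node degree in the *full* interactome.  `beta`
#' scales the reward for collecting prizes, `omega` is the per-tree opening
#' penalty (realized as the cost of the dummy-root edges) and `mu` is a hub
#' penalty discouraging promiscuous high-degree nodes.
#'
#' Defaults (`beta = 1`, `omega = 1`, `mu = 0.005`) are chosen so that a
#' small module of a few prized nodes connected by confident edges (costs
#' around 0.1) is collected as one tree.
#'
#' @param beta positive prize scaling.
#' @param omega nonnegative per-tree penalty.
#' @param mu nonnegative hub (degree) penalty.
#' @param seed integer seed echoed into run manifests; the solver itself is
#'   deterministic.
#' @param max_local_search_rounds cap on local-search improvement rounds.
#' @return a `pcsf_config` list.
#' @export
pcsf_config <- function(beta = 1, omega = 1, mu = 0.005, seed = 1L,
                        max_local_search_rounds = 20L) {
  stopifnot(is.numeric(beta), length(beta) == 1L, beta > 0,
            is.numeric(omega), length(omega) == 1L, omega >= 0,
            is.numeric(mu), length(mu) == 1L, mu >= 0,
            max_local_search_rounds >= 0)
  structure(list(beta = beta, omega = omega, mu = mu,
                 seed = as.integer(seed),
                 max_local_search_rounds = as.integer(max_local_search_rounds)),
            class = "pcsf_config")
}

new_forest <- function(nodes, edges, n_trees, objective = NA_real_) {
  structure(list(nodes = nodes,
                 edges = edges,
                 n_trees = n_trees,
                 objective = objective),
            class = "pcsf_forest")
}

#' @export
print.pcsf_forest <- function(x, ...) {
  cat(sprintf("pcsf_forest: %d nodes, %d edges, %d tree(s), objective %s\n",
              length(x$nodes), nrow(x$edges), x$n_trees,
              format(x$objective)))
  invisible(x)
}

# structural audit used after every solve and inside the objective
validate_forest <- function(forest, interactome) {
  stopifnot(inherits(forest, "pcsf_forest"))
  nodes <- forest$nodes
  edges <- forest$edges
  if (nrow(edges) > 0L) {
    if (!all(edges$u %in% nodes) || !all(edges$v %in% nodes)) {
      stop_value("forest edge endpoint outside the forest node set")
    }
    ik <- edge_key(interactome$edges$u, interactome$edges$v)
    fk <- edge_key(edges$u, edges$v)
    if (anyDuplicated(fk)) stop_value("duplicate edge in forest")
    if (!all(fk %in% ik)) stop_value("forest contains an edge foreign to the interactome")
  }
  if (!all(nodes %in% interactome$nodes$id)) {
    stop_value("forest contains a node foreign to the interactome")
  }
  kappa <- forest_components(nodes, edges)
  # acyclic <=> |E| = |V| - kappa
  if (nrow(edges) != length(nodes) - kappa) {
    stop_value("forest contains a cycle")
  }
  kappa
}

forest_components <- function(nodes, edges) {
  if (length(nodes) == 0L) return(0L)
  idx <- stats::setNames(seq_along(nodes), nodes)
  parent <- seq_along(nodes)
  find <- function(x) {
    while (parent[x] != x) {
      parent[x] <<- parent[parent[x]]
      x <- parent[x]
    }
    x
  }
  if (nrow(edges) > 0L) {
    for (i in seq_len(nrow(edges))) {
      a <- find(idx[[edges$u[i]]])
      b <- find(idx[[edges$v[i]]])
      if (a != b) parent[max(a, b)] <- min(a, b)
    }
  }
  length(unique(vapply(seq_along(nodes), find, 1L)))
}

#' Evaluate the PCSF objective of a forest
#'
#' See [pcsf_config()] for the objective.  The forest is structurally
#' validated first (acyclicity, endpoint closure, edges drawn from the
#' interactome); for the empty forest the value is `beta * sum(p)`.
#'
#' @param forest a `pcsf_forest`.
#' @param interactome the `interactome` the forest lives in.
#' @param prizes a `prize_table` (nodes absent from it have prize 0).
#' @param config a `pcsf_config`.
#' @return the objective value.
#' @export
pcsf_objective <- function(forest, interactome, prizes, config) {
  kappa <- validate_forest(forest, interactome)
  prize_of <- stats::setNames(prizes$prize, prizes$node_id)
  total_prize <- sum(prizes$prize)
  collected <- sum(prize_of[intersect(forest$nodes, names(prize_of))])
  deg <- node_degree(interactome)
  edge_cost <- 0
  if (nrow(forest$edges) > 0L) {
    ik <- edge_key(interactome$edges$u, interactome$edges$v)
    fk <- edge_key(forest$edges$u, forest$edges$v)
    edge_cost <- sum(interactome$edges$cost[match(fk, ik)])
  }
  config$beta * (total_prize - collected) +
    edge_cost +
    config$omega * kappa +
    config$mu * sum(deg[forest$nodes])
}

# deterministic comparison: smaller objective, then fewer nodes, then
# lexicographically smaller sorted node-id vector
forest_better <- function(obj_a, nodes_a, obj_b, nodes_b, tol = 1e-12) {
  if (obj_a < obj_b - tol) return(TRUE)
  if (obj_a > obj_b + tol) return(FALSE)
  if (length(nodes_a) != length(nodes_b)) {
    return(length(nodes_a) < length(nodes_b))
  }
  if (length(nodes_a) == 0L) return(FALSE)
  cmp <- which(nodes_a != nodes_b)
  if (length(cmp) == 0L) return(FALSE)
  nodes_a[cmp[1L]] < nodes_b[cmp[1L]]
}

#' Exact PCSF solution by exhaustive enumeration
#'
#' Enumerates every node subset; for a fixed node set the optimal edge set
#' is a spanning forest over the induced edges taking an edge only when it
#' is cheaper than opening a new tree (greedy matroid argument), so the
#' search over node subsets is exhaustive over all forests.  Intended as a
#' testing oracle for small instances.
#'
#' @param interactome an `interactome` with at most `cap` nodes.
#' @param prizes a `prize_table`.
#' @param config a `pcsf_config`.
#' @param cap maximum instance size (default 12 nodes).
#' @return the globally optimal `pcsf_forest` (ties broken by fewer nodes,
#'   then lexicographic node-id order).
#' @export
brute_force_pcsf <- function(interactome, prizes, config, cap = 12L) {
  stopifnot(inherits(interactome, "interactome"), inherits(config, "pcsf_config"))
  ids <- interactome$nodes$id  # sorted by construction
  n <- length(ids)
  if (n > cap) {
    stop_value("instance has %d nodes, above the brute-force cap of %d", n, cap)
  }
  p <- stats::setNames(numeric(n), ids)
  known <- intersect(prizes$node_id, ids)
  p[known] <- prizes$prize[match(known, prizes$node_id)]
  deg <- node_degree(interactome)[ids]
  eu <- match(interactome$edges$u, ids)
  ev <- match(interactome$edges$v, ids)
  ecost <- interactome$edges$cost
  eord <- order(ecost, eu, ev)
  eu <- eu[eord]; ev <- ev[eord]; ecost <- ecost[eord]
  total_prize <- sum(p)
  beta <- config$beta; omega <- config$omega; mu <- config$mu

  best_obj <- Inf
  best_nodes <- character()
  best_edges <- integer()
  for (mask in 0:(2^n - 1)) {
    inset <- as.logical(bitwAnd(mask, 2^(seq_len(n) - 1L)))
    S <- which(inset)
    forf <- beta * (total_prize - sum(p[S]))
    hub <- mu * sum(deg[S])
    ecost_sum <- 0
    chosen <- integer()
    if (length(S) > 1L) {
      parent <- seq_len(n)
      find <- function(x) {
        while (parent[x] != x) {
          parent[x] <<- parent[parent[x]]
          x <- parent[x]
        }
        x
      }
      for (e in seq_along(eu)) {
        if (ecost[e] >= omega) break  # sorted: nothing cheaper follows
        if (inset[eu[e]] && inset[ev[e]]) {
          a <- find(eu[e]); b <- find(ev[e])
          if (a != b) {
            parent[max(a, b)] <- min(a, b)
            ecost_sum <- ecost_sum + ecost[e]
            chosen <- c(chosen, e)
          }
        }
      }
    }
    kappa <- length(S) - length(chosen)
    obj <- forf + ecost_sum + omega * kappa + hub
    if (forest_better(obj, ids[S], best_obj, best_nodes)) {
      best_obj <- obj
      best_nodes <- ids[S]
      best_edges <- chosen
    }
  }
  edges <- data.frame(u = ids[eu[best_edges]], v = ids[ev[best_edges]],
                      stringsAsFactors = FALSE)
  if (nrow(edges) > 0L) {
    swap <- edges$u > edges$v
    tmp <- edges$u[swap]; edges$u[swap] <- edges$v[swap]; edges$v[swap] <- tmp
    edges <- edges[order(edges$u, edges$v), , drop = FALSE]
    rownames(edges) <- NULL
  }
  fo <- new_forest(best_nodes, edges,
                   forest_components(best_nodes, edges))
  fo$objective <- pcsf_objective(fo, interactome, prizes, config)
  fo
}

# Precompute index structures reused across many solves on one interactome.
pcsf_prepare <- function(interactome, config) {
  ids <- interactome$nodes$id
  list(
    ids = ids,
    eu = match(interactome$edges$u, ids) - 1L,
    ev = match(interactome$edges$v, ids) - 1L,
    cost = interactome$edges$cost,
    deg = as.numeric(node_degree(interactome)[ids]),
    config = config
  )
}

# Fast solve on prepared structures; `prize_vec` is aligned to prep$ids and
# `cost` may be a perturbed copy of prep$cost.
pcsf_solve_prepared <- function(prep, prize_vec, cost = prep$cost) {
  cfg <- prep$config
  netprize <- cfg$beta * prize_vec - cfg$mu * prep$deg
  res <- pcsf_solve_core(length(prep$ids), prep$eu, prep$ev, cost,
                         netprize, cfg$omega,
                         cfg$max_local_search_rounds)
  list(nodes = prep$ids[res$nodes + 1L], edge_idx = res$edge_idx + 1L)
}

#' Solve the PCSF problem heuristically
#'
#' A dummy root is connected to every prized node by an edge of cost
#' `omega`; a rooted Steiner tree is grown by shortest-path attachment of
#' prized nodes, optimally pruned on the tree (strong pruning), and
#' polished by a bounded local search (profitable single-node additions,
#' spanning-forest re-optimization of the edge set, re-pruning).  Removing
#' the root yields the forest.  The solver is fully deterministic: the same
#' inputs always give the same forest.
#'
#' Prize-table entries whose ids are not in the interactome are dropped
#' with a message.  An empty prize table yields the empty forest with a
#' warning.
#'
#' @param interactome an `interactome`.
#' @param prizes a `prize_table`.
#' @param config a `pcsf_config`.
#' @return a `pcsf_forest`; its objective never exceeds that of the empty
#'   forest.
#' @export
solve_pcsf <- function(interactome, prizes, config = pcsf_config()) {
  stopifnot(inherits(interactome, "interactome"), inherits(config, "pcsf_config"))
  unknown <- setdiff(prizes$node_id, interactome$nodes$id)
  if (length(unknown) > 0L) {
    message(sprintf("dropping %d prize id(s) absent from the interactome: %s",
                    length(unknown),
                    paste(utils::head(unknown, 5L), collapse = ", ")))
    prizes <- prizes[!prizes$node_id %in% unknown, , drop = FALSE]
  }
  if (nrow(prizes) == 0L) {
    warning("empty prize table: returning the empty forest")
    fo <- new_forest(character(), data.frame(u = character(), v = character(),
                                             stringsAsFactors = FALSE), 0L)
    fo$objective <- 0
    return(fo)
  }
  prep <- pcsf_prepare(interactome, config)
  prize_vec <- numeric(length(prep$ids))
  prize_vec[match(prizes$node_id, prep$ids)] <- prizes$prize
  sol <- pcsf_solve_prepared(prep, prize_vec)
  edges <- interactome$edges[sol$edge_idx, c("u", "v"), drop = FALSE]
  rownames(edges) <- NULL
  fo <- new_forest(sol$nodes, edges, forest_components(sol$nodes, edges))
  fo$objective <- pcsf_objective(fo, interactome, prizes, config)
  empty_obj <- config$beta * sum(prizes$prize)
  if (fo$objective > empty_obj + 1e-9) {
    # the empty forest is always feasible; never return anything worse
    fo <- new_forest(character(), data.frame(u = character(), v = character(),
                                             stringsAsFactors = FALSE), 0L,
                     empty_obj)
  }
  fo
}

#' Serialize a PCSF solution
#'
#' Writes `solution_nodes.tsv` (id, kind, prize, in-solution degree),
#' `solution_edges.tsv` and `solution.graphml` under `dir`.
#'
#' @param forest a `pcsf_forest`.
#' @param interactome the `interactome` it was solved on.
#' @param prizes the `prize_table` used.
#' @param dir output directory.
#' @param prefix file-name prefix (default `"solution"`).
#' @return invisibly, the paths written.
#' @export
write_forest <- function(forest, interactome, prizes, dir,
                         prefix = "solution") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  kind_of <- stats::setNames(interactome$nodes$kind, interactome$nodes$id)
  prize_of <- stats::setNames(prizes$prize, prizes$node_id)
  indeg <- table(c(forest$edges$u, forest$edges$v))
  nodes <- data.frame(
    id = forest$nodes,
    kind = unname(kind_of[forest$nodes]),
    prize = ifelse(forest$nodes %in% names(prize_of),
                   unname(prize_of[forest$nodes]), 0),
    in_solution_degree = ifelse(forest$nodes %in% names(indeg),
                                as.integer(indeg[forest$nodes]), 0L),
    stringsAsFactors = FALSE
  )
  paths <- file.path(dir, paste0(prefix, c("_nodes.tsv", "_edges.tsv",
                                           ".graphml")))
  write.table(nodes, paths[1L], sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(forest$edges, paths[2L], sep = "\t", quote = FALSE,
              row.names = FALSE)
  g <- igraph::graph_from_data_frame(forest$edges, directed = FALSE,
                                     vertices = nodes)
  igraph::write_graph(g, paths[3L], format = "graphml")
  invisible(paths)
}
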