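#' Node kinds recognised in the composite interactome
#' @keywords internal
NODE_KINDS <- c("protein", "metabolite", "peak", "phosphosite", "tf")

#' Convert interaction confidences to edge costs
#'
#' The optimizer minimizes edge cost, so confident interactions must be
#' cheap.  The mapping is `cost = max(1 - confidence, epsilon)`: monotone
#' decreasing in confidence and bounded away from zero, as the solver
#' requires strictly positive costs.
#'
#' @param confidence numeric vector in \[0, 1\].
#' @param epsilon positive floor applied to the cost (default `1e-6`).
#' @return numeric vector of strictly positive costs.
#' @examples
#' confidence_to_cost(c(0, 0.9, 1))
#' @export
confidence_to_cost <- function(confidence, epsilon = 1e-6) {
  if (!is.numeric(epsilon) || length(epsilon) != 1L || epsilon <= 0) {
    stop_value("`epsilon` must be a single positive number")
  }
  if (!is.numeric(confidence) || anyNA(confidence) ||
      any(confidence < 0 | confidence > 1)) {
    bad <- which(is.na(confidence) | confidence < 0 | confidence > 1)[1L]
    stop_value("confidence must lie in [0, 1]; element %d is %s",
               bad, format(confidence[bad]))
  }
  pmax(1 - confidence, epsilon)
}

#' Load one interactome layer from a TSV edge table
#'
#' The table must be tab-separated with header columns `source`, `target`
#' and `confidence`.  Self-loop rows are dropped (and counted in a
#' message); costs are derived with [confidence_to_cost()].
#'
#' @param path path to the TSV file.
#' @param kind_u,kind_v node kind of the source / target column, one of
#'   `"protein"`, `"metabolite"`, `"peak"`, `"phosphosite"`, `"tf"`.
#' @param layer name of the layer, recorded on every edge.
#' @param epsilon cost floor passed to [confidence_to_cost()].
#' @return a `data.frame` of edges with columns `u`, `v`, `kind_u`,
#'   `kind_v`, `confidence`, `cost`, `layer`, suitable for
#'   [compose_interactome()].
#' @export
load_edge_table <- function(path, kind_u, kind_v, layer, epsilon = 1e-6) {
  kind_u <- match.arg(kind_u, NODE_KINDS)
  kind_v <- match.arg(kind_v, NODE_KINDS)
  tab <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  required <- c("source", "target", "confidence")
  missing_cols <- setdiff(required, names(tab))
  if (length(missing_cols) > 0L) {
    stop_value("edge table '%s' is missing required column(s): %s",
               path, paste(missing_cols, collapse = ", "))
  }
  conf <- suppressWarnings(as.numeric(tab$confidence))
  bad <- which(is.na(conf) | conf < 0 | conf > 1)
  if (length(bad) > 0L) {
    stop_value("edge table '%s': confidence out of [0, 1] at row %d (value %s)",
               path, bad[1L], as.character(tab$confidence[bad[1L]]))
  }
  edges <- data.frame(
    u = as.character(tab$source),
    v = as.character(tab$target),
    kind_u = kind_u,
    kind_v = kind_v,
    confidence = conf,
    cost = confidence_to_cost(conf, epsilon),
    layer = layer,
    stringsAsFactors = FALSE
  )
  loops <- edges$u == edges$v
  if (any(loops)) {
    message(sprintf("layer '%s': dropped %d self-loop row(s)", layer, sum(loops)))
    edges <- edges[!loops, , drop = FALSE]
  }
  rownames(edges) <- NULL
  edges
}

#' Compose interactome layers into one undirected graph
#'
#' Layers are unioned; duplicate undirected edges are collapsed keeping the
#' minimum cost (the most confident evidence wins); node kinds are
#' reconciled across layers and a conflict is an error naming the offending
#' identifier.
#'
#' @param edge_lists a list of edge `data.frame`s as produced by
#'   [load_edge_table()] or [match_peaks()] (each with columns `u`, `v`,
#'   `kind_u`, `kind_v`, `confidence`, `cost`, `layer`).
#' @return an object of class `interactome`: a list with elements
#'   `nodes` (`id`, `kind`, `layer_origin`), `edges` (`u`, `v`,
#'   `confidence`, `cost`, `layer`) and `layer_manifest` (`layer`,
#'   `n_edges`).
#' @export
compose_interactome <- function(edge_lists) {
  if (is.data.frame(edge_lists)) edge_lists <- list(edge_lists)
  stopifnot(length(edge_lists) > 0L)
  cols <- c("u", "v", "kind_u", "kind_v", "confidence", "cost", "layer")
  edge_lists <- lapply(edge_lists, function(e) {
    missing_cols <- setdiff(cols, names(e))
    if (length(missing_cols) > 0L) {
      stop_value("edge list missing column(s): %s",
                 paste(missing_cols, collapse = ", "))
    }
    e[, cols, drop = FALSE]
  })
  all_edges <- do.call(rbind, edge_lists)
  if (any(all_edges$cost <= 0)) stop_value("all edge costs must be positive")
  if (any(all_edges$u == all_edges$v)) stop_value("self loops are not allowed")

  # node kind reconciliation
  node_tab <- rbind(
    data.frame(id = all_edges$u, kind = all_edges$kind_u,
               layer_origin = all_edges$layer, stringsAsFactors = FALSE),
    data.frame(id = all_edges$v, kind = all_edges$kind_v,
               layer_origin = all_edges$layer, stringsAsFactors = FALSE)
  )
  kinds_by_id <- tapply(node_tab$kind, node_tab$id,
                        function(k) unique(k), simplify = FALSE)
  conflict <- names(kinds_by_id)[vapply(kinds_by_id, length, 1L) > 1L]
  if (length(conflict) > 0L) {
    stop_value("node id '%s' declared with conflicting kinds: %s",
               conflict[1L],
               paste(kinds_by_id[[conflict[1L]]], collapse = ", "))
  }
  ids <- sort(unique(node_tab$id))
  kinds <- vapply(kinds_by_id[ids], `[`, "", 1L)
  origin <- tapply(node_tab$layer_origin, node_tab$id, function(l) {
    paste(sort(unique(unlist(strsplit(l, ",", fixed = TRUE)))),
          collapse = ",")
  })
  nodes <- data.frame(id = ids, kind = unname(kinds),
                      layer_origin = unname(origin[ids]),
                      stringsAsFactors = FALSE)

  # canonical undirected orientation, then collapse duplicates by min cost
  a <- pmin(all_edges$u, all_edges$v)
  b <- pmax(all_edges$u, all_edges$v)
  key <- paste(a, b, sep = "\r")
  ord <- order(key, all_edges$cost)
  a <- a[ord]; b <- b[ord]
  conf <- all_edges$confidence[ord]
  cost <- all_edges$cost[ord]
  key <- key[ord]
  first <- !duplicated(key)
  layer_joined <- tapply(all_edges$layer[ord], key, function(l) {
    paste(sort(unique(unlist(strsplit(l, ",", fixed = TRUE)))),
          collapse = ",")
  })
  edges <- data.frame(
    u = a[first], v = b[first],
    confidence = conf[first], cost = cost[first],
    layer = unname(layer_joined[key[first]]),
    stringsAsFactors = FALSE
  )
  edges <- edges[order(edges$u, edges$v), , drop = FALSE]
  rownames(edges) <- NULL

  manifest_tab <- table(all_edges$layer)
  layer_manifest <- data.frame(layer = names(manifest_tab),
                               n_edges = as.integer(manifest_tab),
                               stringsAsFactors = FALSE)

  structure(
    list(nodes = nodes, edges = edges, layer_manifest = layer_manifest),
    class = "interactome"
  )
}

#' @export
print.interactome <- function(x, ...) {
  cat(sprintf("interactome: %d nodes, %d edges, %d layer(s)\n",
              nrow(x$nodes), nrow(x$edges), nrow(x$layer_manifest)))
  kt <- table(x$nodes$kind)
  cat("  kinds:", paste(sprintf("%s=%d", names(kt), kt), collapse = ", "), "\n")
  invisible(x)
}

#' Recover a composable edge list from a composed interactome
#'
#' Useful to re-enter [compose_interactome()] (composition is idempotent).
#' @param interactome an `interactome`.
#' @return edge `data.frame` in the [load_edge_table()] layout.
#' @export
interactome_edgelist <- function(interactome) {
  stopifnot(inherits(interactome, "interactome"))
  kind_of <- stats::setNames(interactome$nodes$kind, interactome$nodes$id)
  e <- interactome$edges
  data.frame(u = e$u, v = e$v,
             kind_u = unname(kind_of[e$u]), kind_v = unname(kind_of[e$v]),
             confidence = e$confidence, cost = e$cost, layer = e$layer,
             stringsAsFactors = FALSE)
}

#' Interactome node degrees
#' @param interactome an `interactome`.
#' @return named integer vector of degrees over all nodes.
#' @export
node_degree <- function(interactome) {
  stopifnot(inherits(interactome, "interactome"))
  deg <- table(c(interactome$edges$u, interactome$edges$v))
  out <- stats::setNames(integer(nrow(interactome$nodes)), interactome$nodes$id)
  out[names(deg)] <- as.integer(deg)
  out
}

#' Convert an interactome to an igraph object
#' @param interactome an `interactome`.
#' @return an undirected `igraph` graph with `kind`, `confidence`, `cost`
#'   and `layer` attributes.
#' @export
as_igraph <- function(interactome) {
  stopifnot(inherits(interactome, "interactome"))
  igraph::graph_from_data_frame(
    interactome$edges,
    directed = FALSE,
    vertices = interactome$nodes
  )
}

#' Serialize an interactome to disk
#'
#' Writes `nodes.tsv`, `edges.tsv` and `interactome.graphml` under `dir`.
#' @param interactome an `interactome`.
#' @param dir output directory (created if absent).
#' @return invisibly, the paths written.
#' @export
write_interactome <- function(interactome, dir) {
  stopifnot(inherits(interactome, "interactome"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- file.path(dir, c("nodes.tsv", "edges.tsv", "interactome.graphml"))
  write.table(interactome$nodes, paths[1L], sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(interactome$edges, paths[2L], sep = "\t",
              quote = FALSE, row.names = FALSE)
  igraph::write_graph(as_igraph(interactome), paths[3L], format = "graphml")
  invisible(paths)
}
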