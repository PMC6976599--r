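#' Hypergeometric upper-tail probability
#'
#' `P(X >= k)` where `X` counts successes in `n` draws without replacement
#' from a population of `N` containing `K` successes.  Evaluated exactly
#' via the log-gamma form of the hypergeometric distribution (no
#' simulation).
#'
#' @param k observed overlap (0 <= k <= min(K, n)).
#' @param K successes in the population.
#' @param n draws.
#' @param N population size.
#' @return the upper-tail probability.
#' @examples
#' hypergeom_tail(4, 4, 5, 10)  # 6/252
#' @export
hypergeom_tail <- function(k, K, n, N) {
  if (any(c(k, K, n, N) < 0) || K > N || n > N || k > min(K, n)) {
    stop_value("inconsistent hypergeometric counts: k=%d K=%d n=%d N=%d",
               k, K, n, N)
  }
  if (k == 0) return(1)
  phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

#' Read a GMT gene-set collection
#'
#' @param path GMT file (tab-separated: set id, description, members...).
#' @return list of gene sets, each `list(set_id, name, members)`.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  sets <- lapply(lines, function(l) {
    parts <- strsplit(l, "\t", fixed = TRUE)[[1L]]
    if (length(parts) < 3L) {
      stop_value("malformed GMT line (need id, description, >=1 member): %s",
                 substr(l, 1L, 60L))
    }
    list(set_id = parts[1L], name = parts[2L],
         members = unique(parts[-(1:2)]))
  })
  ids <- vapply(sets, `[[`, "", "set_id")
  if (anyDuplicated(ids)) stop_value("duplicate set_id in GMT: %s",
                                     ids[duplicated(ids)][1L])
  sets
}

#' Write a GMT gene-set collection
#' @param sets list of gene sets as returned by [read_gmt()].
#' @param path output path.
#' @export
write_gmt <- function(sets, path) {
  lines <- vapply(sets, function(s) {
    paste(c(s$set_id, s$name, s$members), collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' Hypergeometric gene-set enrichment of a node set
#'
#' Each gene set is intersected with the universe and tested for
#' over-representation in `network_nodes` with the hypergeometric upper
#' tail; p-values are BH-adjusted across the collection and flagged
#' significant at `p_adj < alpha`.
#'
#' @param network_nodes character vector of node ids (must lie inside
#'   `universe`).
#' @param collection list of gene sets (see [read_gmt()]).
#' @param universe background node ids.
#' @param alpha significance level on the adjusted p-value (default 0.05).
#' @return `data.frame` with columns `set_id`, `name`, `n_set`, `overlap`,
#'   `p`, `p_adj`, `significant`, sorted by `p_adj` then `set_id`.
#' @export
enrich <- function(network_nodes, collection, universe, alpha = 0.05) {
  universe <- unique(universe)
  if (length(universe) == 0L) stop_value("universe is empty")
  outside <- setdiff(network_nodes, universe)
  if (length(outside) > 0L) {
    stop_value("network node '%s' is outside the universe", outside[1L])
  }
  network_nodes <- unique(network_nodes)
  N <- length(universe)
  n <- length(network_nodes)
  rows <- lapply(collection, function(s) {
    members <- intersect(s$members, universe)
    K <- length(members)
    k <- length(intersect(members, network_nodes))
    p <- if (K == 0L) 1 else hypergeom_tail(k, K, n, N)
    data.frame(set_id = s$set_id, name = s$name, n_set = K, overlap = k,
               p = p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_adj <- p.adjust(out$p, method = "BH")
  out$significant <- out$p_adj < alpha
  out <- out[order(out$p_adj, out$set_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Default enrichment universe of an interactome
#'
#' All nodes of kind protein, metabolite or tf (peaks and phosphosites are
#' measurement proxies, not pathway members).
#' @param interactome an `interactome`.
#' @return character vector of node ids.
#' @export
enrichment_universe <- function(interactome) {
  stopifnot(inherits(interactome, "interactome"))
  interactome$nodes$id[interactome$nodes$kind %in%
                         c("protein", "metabolite", "tf")]
}
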