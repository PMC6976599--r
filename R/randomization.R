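#' Perturb interactome edge costs with Gaussian noise
#'
#' Each cost is replaced by `max(cost + g, epsilon)` where `g` is a
#' zero-mean normal draw with standard deviation `sigma`.  Deterministic
#' per seed; `sigma = 0` returns the interactome unchanged.
#'
#' @param interactome an `interactome`.
#' @param sigma noise standard deviation (>= 0, default 0.1).
#' @param seed integer seed.
#' @param epsilon positive lower clamp on costs.
#' @return a perturbed copy of the interactome.
#' @export
perturb_costs <- function(interactome, sigma = 0.1, seed = 1L,
                          epsilon = 1e-6) {
  stopifnot(inherits(interactome, "interactome"),
            is.numeric(sigma), length(sigma) == 1L, sigma >= 0)
  if (sigma == 0) return(interactome)
  g <- with_seed(seed, rnorm(nrow(interactome$edges), 0, sigma))
  interactome$edges$cost <- pmax(interactome$edges$cost + g, epsilon)
  interactome
}

#' Reassign prizes to random, degree-matched nodes
#'
#' Used for specificity measurements: the multiset of prize values is kept
#' but the values are moved to nodes sampled without replacement,
#' degree-matched within decile bins of interactome degree (so hub nodes
#' cannot trivially fail specificity just by being hubs).  When a bin runs
#' out of candidates, sampling for that entry falls back to the global
#' unused pool (logged).
#'
#' @param prizes a `prize_table` whose ids are interactome nodes.
#' @param interactome an `interactome`.
#' @param seed integer seed.
#' @param n_bins number of degree-quantile bins (default 10).
#' @return a `prize_table` of the same size with the same prize values on
#'   new node ids.
#' @export
random_prizes <- function(prizes, interactome, seed = 1L, n_bins = 10L) {
  stopifnot(inherits(interactome, "interactome"))
  ids <- interactome$nodes$id
  if (nrow(prizes) > length(ids)) {
    stop_value("prize table larger than the interactome node set")
  }
  deg <- node_degree(interactome)[ids]
  breaks <- unique(quantile(deg, probs = seq(0, 1, length.out = n_bins + 1L)))
  bin <- if (length(breaks) > 2L) {
    cut(deg, breaks = breaks, include.lowest = TRUE, labels = FALSE)
  } else {
    rep(1L, length(deg))
  }
  names(bin) <- ids
  src <- prizes$node_id
  missing_src <- setdiff(src, ids)
  if (length(missing_src) > 0L) {
    stop_value("prize id '%s' is not an interactome node", missing_src[1L])
  }
  with_seed(seed, {
    used <- character(0)
    target <- character(length(src))
    n_fallback <- 0L
    for (i in seq_along(src)) {
      want_bin <- bin[[src[i]]]
      pool <- ids[bin == want_bin & !(ids %in% used)]
      if (length(pool) == 0L) {
        pool <- setdiff(ids, used)
        n_fallback <- n_fallback + 1L
      }
      pick <- if (length(pool) == 1L) pool else sample(pool, 1L)
      target[i] <- pick
      used <- c(used, pick)
    }
    if (n_fallback > 0L) {
      message(sprintf("random_prizes: %d entr(ies) fell back to global sampling",
                      n_fallback))
    }
    out <- data.frame(node_id = target, prize = prizes$prize,
                      layers = prizes$layers, stringsAsFactors = FALSE)
    out <- out[order(out$node_id), , drop = FALSE]
    rownames(out) <- NULL
    class(out) <- c("prize_table", "data.frame")
    out
  })
}

#' Score nodes by robustness and specificity across randomized reruns
#'
#' Robustness of a node is the fraction of edge-noise reruns whose solution
#' contains it; specificity is one minus the fraction of random-prize
#' reruns containing it (high specificity = the node is not attracted by
#' arbitrary inputs).  Every node appearing in any run -- plus any ids in
#' `extra_nodes` -- is scored.
#'
#' @param noisy_forests list of `pcsf_forest`s (or character node vectors)
#'   from noisy reruns.
#' @param random_forests list from random-prize reruns.
#' @param extra_nodes additional node ids to score even if absent from all
#'   runs (typically the base solution's nodes).
#' @return `data.frame` with columns `node_id`, `robustness`,
#'   `specificity`, `n_runs`.
#' @export
score_nodes <- function(noisy_forests, random_forests, extra_nodes = character()) {
  if (length(noisy_forests) == 0L || length(random_forests) == 0L) {
    stop_value("both run lists must be nonempty")
  }
  get_nodes <- function(f) if (inherits(f, "pcsf_forest")) f$nodes else as.character(f)
  noisy <- lapply(noisy_forests, get_nodes)
  rand <- lapply(random_forests, get_nodes)
  all_ids <- sort(unique(c(unlist(noisy), unlist(rand), extra_nodes)))
  n_noisy <- length(noisy)
  n_rand <- length(rand)
  noisy_count <- table(factor(unlist(lapply(noisy, unique)), levels = all_ids))
  rand_count <- table(factor(unlist(lapply(rand, unique)), levels = all_ids))
  data.frame(
    node_id = all_ids,
    robustness = as.numeric(noisy_count) / n_noisy,
    specificity = 1 - as.numeric(rand_count) / n_rand,
    n_runs = n_noisy,
    stringsAsFactors = FALSE
  )
}

#' Filter a base solution by robustness and specificity
#'
#' Keeps the nodes of the base forest with `robustness >=
#' min_robustness` *and* `specificity >= min_specificity` (the comparison
#' is inclusive), retains the induced edges among survivors, and recounts
#' trees (the filtered network may split).
#'
#' @param base_forest the unperturbed `pcsf_forest`.
#' @param scores node scores from [score_nodes()]; every base node must be
#'   scored.
#' @param min_robustness,min_specificity thresholds in \[0, 1\]
#'   (defaults 0.40 / 0.40).
#' @return the filtered `pcsf_forest` (objective is not recomputed and set
#'   to `NA`).
#' @export
filter_nodes <- function(base_forest, scores,
                         min_robustness = 0.40, min_specificity = 0.40) {
  stopifnot(inherits(base_forest, "pcsf_forest"),
            min_robustness >= 0, min_robustness <= 1,
            min_specificity >= 0, min_specificity <= 1)
  unscored <- setdiff(base_forest$nodes, scores$node_id)
  if (length(unscored) > 0L) {
    stop_value("base-forest node '%s' has no robustness/specificity score",
               unscored[1L])
  }
  m <- match(base_forest$nodes, scores$node_id)
  keep <- scores$robustness[m] >= min_robustness &
    scores$specificity[m] >= min_specificity
  kept_nodes <- base_forest$nodes[keep]
  e <- base_forest$edges
  kept_edges <- e[e$u %in% kept_nodes & e$v %in% kept_nodes, , drop = FALSE]
  rownames(kept_edges) <- NULL
  new_forest(kept_nodes, kept_edges,
             forest_components(kept_nodes, kept_edges))
}

#' Robustness/specificity randomization around a base PCSF solve
#'
#' Solves the unperturbed instance, then reruns the solver `n_runs` times
#' under edge-cost noise (robustness) and `n_runs` times with
#' degree-matched random prize placements (specificity), scores every node
#' and filters the base solution at the given thresholds.
#'
#' @param interactome an `interactome`.
#' @param prizes a `prize_table`.
#' @param config a `pcsf_config`.
#' @param n_runs reruns per randomization arm (default 100).
#' @param sigma edge-cost noise standard deviation (default 0.1).
#' @param min_robustness,min_specificity filtering thresholds
#'   (defaults 0.40 / 0.40).
#' @param seed integer seed; run `i` uses `seed + i` (noise) and
#'   `seed + 500000 + i` (random prizes).
#' @return list with elements `base` (unperturbed `pcsf_forest`), `scores`
#'   (from [score_nodes()]), `filtered` (`pcsf_forest`), `n_runs`.
#' @export
run_randomization <- function(interactome, prizes, config = pcsf_config(),
                              n_runs = 100L, sigma = 0.1,
                              min_robustness = 0.40, min_specificity = 0.40,
                              seed = config$seed) {
  stopifnot(n_runs >= 1L)
  base <- solve_pcsf(interactome, prizes, config)
  prizes <- prizes[prizes$node_id %in% interactome$nodes$id, , drop = FALSE]
  prep <- pcsf_prepare(interactome, config)
  prize_vec <- numeric(length(prep$ids))
  prize_vec[match(prizes$node_id, prep$ids)] <- prizes$prize

  noisy <- vector("list", n_runs)
  for (i in seq_len(n_runs)) {
    g <- with_seed(seed + i, rnorm(length(prep$cost), 0, sigma))
    cost_i <- pmax(prep$cost + g, 1e-6)
    noisy[[i]] <- pcsf_solve_prepared(prep, prize_vec, cost_i)$nodes
  }
  rand <- vector("list", n_runs)
  for (i in seq_len(n_runs)) {
    rp <- random_prizes(prizes, interactome, seed = seed + 500000L + i)
    rvec <- numeric(length(prep$ids))
    rvec[match(rp$node_id, prep$ids)] <- rp$prize
    rand[[i]] <- pcsf_solve_prepared(prep, rvec)$nodes
  }
  scores <- score_nodes(noisy, rand, extra_nodes = base$nodes)
  filtered <- filter_nodes(base, scores, min_robustness, min_specificity)
  list(base = base, scores = scores, filtered = filtered, n_runs = n_runs)
}
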