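# Benchmark experiments on synthetic instances with planted ground truth.
# These wrappers define the study conditions used by the test suite and by
# scripts/acceptance.R, so the experiments are reproducible from one entry
# point.

#' Random small PCSF instance for solver-vs-oracle comparisons
#'
#' A connected graph on `n_nodes` (random spanning tree plus random extra
#' edges), random edge costs uniform on (0.05, 0.6) and prizes uniform on
#' (0, 3) for a random subset of nodes.
#'
#' @param n_nodes instance size.
#' @param seed integer seed.
#' @return list with `interactome` and `prizes`.
#' @export
random_small_instance <- function(n_nodes, seed = 1L) {
  with_seed(seed, {
    ids <- sprintf("v%02d", seq_len(n_nodes))
    eu <- integer(0); ev <- integer(0)
    for (i in 2:n_nodes) {  # random spanning tree: connectivity guaranteed
      eu <- c(eu, i)
      ev <- c(ev, sample(i - 1L, 1L))
    }
    n_extra <- sample(0:n_nodes, 1L)
    have <- paste(pmin(eu, ev), pmax(eu, ev))
    tries <- 0L
    while (n_extra > 0L && tries < 50L) {
      tries <- tries + 1L
      cand <- sort(sample(n_nodes, 2L))
      key <- paste(cand[1L], cand[2L])
      if (!key %in% have) {
        eu <- c(eu, cand[2L]); ev <- c(ev, cand[1L])
        have <- c(have, key)
        n_extra <- n_extra - 1L
      }
    }
    conf <- 1 - runif(length(eu), 0.05, 0.6)  # cost = 1 - confidence
    edges <- data.frame(u = ids[eu], v = ids[ev],
                        kind_u = "protein", kind_v = "protein",
                        confidence = conf, cost = 1 - conf,
                        layer = "sim", stringsAsFactors = FALSE)
    ix <- compose_interactome(list(edges))
    n_prized <- sample(seq_len(n_nodes), 1L)
    prized <- sort(sample(ids, n_prized))
    pt <- data.frame(node_id = prized,
                     prize = runif(n_prized, 0, 3),
                     layers = "sim", stringsAsFactors = FALSE)
    class(pt) <- c("prize_table", "data.frame")
    list(interactome = ix, prizes = pt)
  })
}

#' Compare the heuristic solver against the exact oracle
#'
#' Generates `n_instances` random connected instances of at most
#' `max_nodes` nodes, solves each with [solve_pcsf()] and
#' [brute_force_pcsf()], and summarizes the objective ratios.
#'
#' @param n_instances number of instances (default 200).
#' @param max_nodes maximum instance size (default 9).
#' @param seed integer seed.
#' @param config a `pcsf_config`.
#' @return list with `ratios` (heuristic / optimal, offset so both are
#'   positive), `exact_fraction`, `worst_ratio`.
#' @export
solver_oracle_benchmark <- function(n_instances = 200L, max_nodes = 9L,
                                    seed = 1L, config = pcsf_config()) {
  sizes <- with_seed(seed, sample(4:max_nodes, n_instances, replace = TRUE))
  ratios <- numeric(n_instances)
  exact <- logical(n_instances)
  for (i in seq_len(n_instances)) {
    inst <- random_small_instance(sizes[i], seed = seed + 1000L + i)
    heur <- solve_pcsf(inst$interactome, inst$prizes, config)
    opt <- brute_force_pcsf(inst$interactome, inst$prizes, config)
    ratios[i] <- if (opt$objective > 0) heur$objective / opt$objective else 1
    exact[i] <- abs(heur$objective - opt$objective) <= 1e-9
  }
  list(ratios = ratios,
       exact_fraction = mean(exact),
       worst_ratio = max(ratios))
}

#' Planted-module recovery benchmark
#'
#' Generates a scale-free interactome, plants one connected module whose
#' members carry elevated differential signal, adds null features, runs
#' prize derivation, the PCSF solve, randomization scoring and 40/40
#' filtering, and scores the filtered network against the planted module.
#' Optionally adds decoy prized nodes (uniformly placed non-module nodes
#' whose `log2fc` comes from the null effect model Normal(0, 0.2)) to
#' measure decoy rejection.
#'
#' @param seed integer seed.
#' @param n_nodes,attachment interactome parameters.
#' @param module_size planted module size.
#' @param effect_mu,effect_sd planted effect size.
#' @param n_null number of null differential features.
#' @param decoy_count decoy prized nodes to add (default 0).
#' @param n_runs randomization reruns per arm.
#' @param sigma edge-noise standard deviation.
#' @param config a `pcsf_config`.
#' @return list with `f1`, `precision`, `recall` (filtered network vs
#'   planted module over prize-eligible nodes), `planted_retained`,
#'   `module_size`, and -- when decoys are present -- `decoys_in_base`,
#'   `decoys_removed`.
#' @export
recovery_benchmark <- function(seed = 1L, n_nodes = 300L, attachment = 2L,
                               module_size = 12L, effect_mu = 2,
                               effect_sd = 0.5, n_null = 100L,
                               decoy_count = 0L, n_runs = 100L, sigma = 0.1,
                               config = pcsf_config()) {
  ix <- generate_interactome(n_nodes, attachment, seed = seed)
  truth <- plant_modules(ix, 1L, module_size, seed = seed + 1L)
  omics <- generate_omics(truth, ix, effect_mu = effect_mu,
                          effect_sd = effect_sd, n_null = n_null,
                          seed = seed + 2L)
  feats <- adjust_differential(omics)
  sig <- suppressMessages(select_differential(feats, 0.05))
  prizes <- assign_prizes(sig)

  module <- names(truth$module_assignments)
  decoys <- character(0)
  if (decoy_count > 0L) {
    pool <- setdiff(ix$nodes$id, c(module, prizes$node_id))
    decoys <- with_seed(seed + 3L, sort(sample(pool, decoy_count)))
    decoy_prize <- with_seed(seed + 4L, abs(rnorm(decoy_count, 0, 0.2)))
    extra <- data.frame(node_id = decoys, prize = decoy_prize,
                        layers = "decoy", stringsAsFactors = FALSE)
    prizes <- rbind(prizes, extra)
    prizes <- prizes[order(prizes$node_id), , drop = FALSE]
    rownames(prizes) <- NULL
    class(prizes) <- c("prize_table", "data.frame")
  }

  rr <- suppressMessages(suppressWarnings(
    run_randomization(ix, prizes, config, n_runs = n_runs, sigma = sigma,
                      seed = seed + 10L)
  ))
  recovered <- rr$filtered$nodes
  tp <- length(intersect(recovered, module))
  precision <- if (length(recovered) > 0L) tp / length(recovered) else 0
  recall <- tp / length(module)
  f1 <- if (precision + recall > 0) {
    2 * precision * recall / (precision + recall)
  } else {
    0
  }
  out <- list(f1 = f1, precision = precision, recall = recall,
              planted_retained = recall, module_size = length(module),
              base_nodes = length(rr$base$nodes),
              filtered_nodes = length(recovered))
  if (decoy_count > 0L) {
    in_base <- intersect(decoys, rr$base$nodes)
    removed <- setdiff(in_base, recovered)
    out$decoys_in_base <- length(in_base)
    out$decoys_removed <- length(removed)
  }
  out
}

#' Peak-matching recall and decoy rejection benchmark
#'
#' Builds a synthetic metabolite database, plants true peaks with ppm
#' noise plus decoys far from every database entry, runs [match_peaks()],
#' and reports recall of true peak-metabolite pairs and the decoy match
#' rate.
#'
#' @param seed integer seed.
#' @param n_metabolites database size.
#' @param n_true number of true peaks.
#' @param decoy_count number of decoy peaks.
#' @param ppm_noise_sd mass-accuracy noise (ppm).
#' @param ppm_tol matching tolerance (ppm).
#' @return list with `recall`, `decoy_match_rate`, `n_peaks`.
#' @export
peak_matching_benchmark <- function(seed = 1L, n_metabolites = 600L,
                                    n_true = 450L, decoy_count = 50L,
                                    ppm_noise_sd = 2, ppm_tol = 10) {
  db <- with_seed(seed, {
    data.frame(met_id = sprintf("met_%04d", seq_len(n_metabolites)),
               monoisotopic_mass = runif(n_metabolites, 100, 900),
               name = "synthetic", stringsAsFactors = FALSE)
  })
  adducts <- default_adducts()
  truth <- structure(
    list(module_assignments = stats::setNames(
           rep(1L, n_true),
           with_seed(seed + 1L, sample(db$met_id, n_true,
                                       replace = FALSE))),
         true_peak_matches = character(0),
         generation_config = list()),
    class = "synthetic_truth"
  )
  pk <- generate_peaks(truth, db, adducts, ppm_noise_sd = ppm_noise_sd,
                       decoy_count = decoy_count, ppm_tol_ref = ppm_tol,
                       seed = seed + 2L)
  matches <- match_peaks(pk$peaks, db, adducts, ppm_tol = ppm_tol)
  truth_map <- pk$truth$true_peak_matches
  hit <- paste(matches$u, matches$v) %in%
    paste(names(truth_map), unname(truth_map))
  recall <- sum(hit) / length(truth_map)
  decoy_ids <- grep("^decoy_", pk$peaks$peak_id, value = TRUE)
  decoy_matched <- sum(decoy_ids %in% matches$u)
  list(recall = recall,
       decoy_match_rate = if (length(decoy_ids) > 0L) {
         decoy_matched / length(decoy_ids)
       } else {
         0
       },
       n_peaks = nrow(pk$peaks))
}

#' Monotonicity of exact solutions in beta and omega
#'
#' On fixed instances, the optimum's total collected prize must be
#' non-decreasing in `beta` and its tree count non-increasing in `omega`.
#' Checked with the exact solver over parameter grids.
#'
#' @param n_instances number of instances (default 20).
#' @param n_nodes instance size (default 8).
#' @param seed integer seed.
#' @param beta_grid,omega_grid parameter grids.
#' @return list with `beta_violations`, `omega_violations` (counts).
#' @export
scalarization_benchmark <- function(n_instances = 20L, n_nodes = 8L,
                                    seed = 1L,
                                    beta_grid = c(0.5, 1, 2, 4, 8),
                                    omega_grid = c(0.25, 0.5, 1, 2, 4)) {
  beta_viol <- 0L
  omega_viol <- 0L
  for (i in seq_len(n_instances)) {
    inst <- random_small_instance(n_nodes, seed = seed + 2000L + i)
    prize_of <- stats::setNames(inst$prizes$prize, inst$prizes$node_id)
    collected <- vapply(beta_grid, function(b) {
      fo <- brute_force_pcsf(inst$interactome, inst$prizes,
                             pcsf_config(beta = b))
      sum(prize_of[intersect(fo$nodes, names(prize_of))])
    }, 0)
    if (any(diff(collected) < -1e-9)) beta_viol <- beta_viol + 1L
    kappas <- vapply(omega_grid, function(w) {
      fo <- brute_force_pcsf(inst$interactome, inst$prizes,
                             pcsf_config(omega = w))
      as.numeric(fo$n_trees)
    }, 0)
    if (any(diff(kappas) > 1e-9)) omega_viol <- omega_viol + 1L
  }
  list(beta_violations = beta_viol, omega_violations = omega_viol)
}
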