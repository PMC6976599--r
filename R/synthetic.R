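#' Generate a scale-free synthetic interactome
#'
#' Preferential attachment: the graph starts from `attachment` isolated
#' seed nodes; each subsequent node attaches to `attachment` distinct
#' existing nodes with probability proportional to degree + 1.  This gives
#' the heavy-tailed degree distribution characteristic of protein
#' interactomes (hubs are exactly what specificity filtering must be
#' stress-tested against) and exactly `(n_nodes - attachment) * attachment`
#' edges, all in one connected component.  Edge confidences are uniform on
#' (0.5, 1); costs follow [confidence_to_cost()].
#'
#' @param n_nodes number of nodes (> `attachment`).
#' @param attachment edges added per new node (default 2).
#' @param kind_mix named proportions over node kinds (default
#'   70% protein, 15% metabolite, 10% phosphosite, 5% tf).
#' @param seed integer seed; the same seed reproduces the same graph.
#' @return an `interactome` with layer `"synthetic"`.
#' @export
generate_interactome <- function(n_nodes, attachment = 2L,
                                 kind_mix = c(protein = 0.70,
                                              metabolite = 0.15,
                                              phosphosite = 0.10,
                                              tf = 0.05),
                                 seed = 1L) {
  m <- as.integer(attachment)
  if (n_nodes < m + 1L) {
    stop_value("n_nodes must be at least attachment + 1 (%d)", m + 1L)
  }
  if (is.null(names(kind_mix)) || !all(names(kind_mix) %in% NODE_KINDS)) {
    stop_value("kind_mix must be named with node kinds")
  }
  with_seed(seed, {
    deg <- integer(n_nodes)
    eu <- integer((n_nodes - m) * m)
    ev <- integer((n_nodes - m) * m)
    k <- 0L
    for (i in (m + 1L):n_nodes) {
      existing <- seq_len(i - 1L)
      targets <- if (length(existing) == m) {
        existing
      } else {
        sample(existing, m, replace = FALSE, prob = deg[existing] + 1)
      }
      for (t in targets) {
        k <- k + 1L
        eu[k] <- i
        ev[k] <- t
        deg[i] <- deg[i] + 1L
        deg[t] <- deg[t] + 1L
      }
    }
    width <- nchar(as.character(n_nodes))
    ids <- sprintf(paste0("n%0", width, "d"), seq_len(n_nodes))
    kinds <- sample(names(kind_mix), n_nodes, replace = TRUE,
                    prob = kind_mix)
    conf <- runif(length(eu), 0.5, 1)
    edges <- data.frame(
      u = ids[eu], v = ids[ev],
      kind_u = kinds[eu], kind_v = kinds[ev],
      confidence = conf, cost = confidence_to_cost(conf),
      layer = "synthetic", stringsAsFactors = FALSE
    )
    compose_interactome(list(edges))
  })
}

#' Plant connected ground-truth modules in an interactome
#'
#' Each module is a connected induced subgraph grown by breadth-first
#' expansion from a random seed node; modules are node-disjoint.  The
#' planted membership is the ground truth that recovery benchmarks score
#' against.
#'
#' @param interactome an `interactome`.
#' @param n_modules number of modules (may be 0).
#' @param module_size nodes per module (>= 2).
#' @param seed integer seed.
#' @return a `synthetic_truth` list: `module_assignments` (named integer
#'   vector, node id -> module index), `true_peak_matches` (named character
#'   vector, filled by [generate_peaks()]), `generation_config`.
#' @export
plant_modules <- function(interactome, n_modules, module_size, seed = 1L) {
  stopifnot(inherits(interactome, "interactome"))
  if (n_modules > 0L && module_size < 2L) {
    stop_value("module_size must be >= 2")
  }
  ids <- interactome$nodes$id
  adj <- split(c(interactome$edges$v, interactome$edges$u),
               c(interactome$edges$u, interactome$edges$v))
  assignments <- integer(0)
  with_seed(seed, {
    taken <- character(0)
    for (mod in seq_len(n_modules)) {
      placed <- FALSE
      candidates <- sample(setdiff(ids, taken))
      for (seed_node in candidates) {
        members <- seed_node
        frontier <- seed_node
        while (length(members) < module_size && length(frontier) > 0L) {
          nbrs <- setdiff(unique(unlist(adj[frontier], use.names = FALSE)),
                          c(members, taken))
          if (length(nbrs) == 0L) break
          need <- module_size - length(members)
          add <- if (length(nbrs) <= need) nbrs else sample(nbrs, need)
          frontier <- add
          members <- c(members, add)
        }
        if (length(members) == module_size) {
          assignments <- c(assignments,
                           stats::setNames(rep(mod, module_size), members))
          taken <- c(taken, members)
          placed <- TRUE
          break
        }
      }
      if (!placed) {
        stop_value("could not place %d disjoint connected module(s) of size %d; try smaller modules",
                   n_modules, module_size)
      }
    }
  })
  structure(
    list(module_assignments = assignments,
         true_peak_matches = character(0),
         generation_config = list(n_modules = n_modules,
                                  module_size = module_size, seed = seed)),
    class = "synthetic_truth"
  )
}

#' Generate differential-omics tables with planted signal
#'
#' Module members carry elevated signal: `|log2fc|` drawn from a positive
#' truncated Normal(`effect_mu`, `effect_sd`) with random sign, and raw
#' p-values uniform on (1e-6, 1e-3).  Null features have `log2fc ~
#' Normal(0, 0.2)` and `p_raw ~ Uniform(0, 1)` (uniform by construction so
#' BH behavior is analytically checkable).  Layers follow node kind
#' (protein -> `protein`, phosphosite -> `phosphosite`, tf -> `tf`,
#' metabolite -> `polar_peak`); metabolite members are reported under
#' their generated peak id when [generate_peaks()] has filled
#' `truth$true_peak_matches`, otherwise under the metabolite id itself.
#'
#' @param truth a `synthetic_truth` from [plant_modules()].
#' @param interactome the `interactome` the modules live in.
#' @param effect_mu mean planted effect size (log2 scale, > 0; default 2).
#' @param effect_sd effect-size spread (default 0.5).
#' @param null_fraction fraction of the null features placed on real
#'   (non-module) interactome nodes; the remainder get unmapped ids
#'   (default 1).
#' @param n_null number of null features (default 100).
#' @param seed integer seed.
#' @return `data.frame` with columns `feature_id`, `layer`, `log2fc`,
#'   `p_raw`.
#' @export
generate_omics <- function(truth, interactome, effect_mu = 2,
                           effect_sd = 0.5, null_fraction = 1,
                           n_null = 100L, seed = 1L) {
  stopifnot(inherits(truth, "synthetic_truth"),
            inherits(interactome, "interactome"),
            effect_mu > 0, effect_sd >= 0,
            null_fraction >= 0, null_fraction <= 1, n_null >= 0)
  kind_of <- stats::setNames(interactome$nodes$kind, interactome$nodes$id)
  layer_of_kind <- c(protein = "protein", phosphosite = "phosphosite",
                     tf = "tf", metabolite = "polar_peak", peak = "polar_peak")
  members <- names(truth$module_assignments)
  peak_of_met <- if (length(truth$true_peak_matches) > 0L) {
    stats::setNames(names(truth$true_peak_matches), truth$true_peak_matches)
  } else {
    character(0)
  }
  with_seed(seed, {
    rows <- list()
    if (length(members) > 0L) {
      effect <- abs(rnorm(length(members), effect_mu, effect_sd))
      effect[effect == 0] <- effect_mu
      sign <- sample(c(-1, 1), length(members), replace = TRUE)
      fid <- members
      is_met <- kind_of[members] == "metabolite"
      mapped <- is_met & members %in% names(peak_of_met)
      fid[mapped] <- unname(peak_of_met[members[mapped]])
      rows$signal <- data.frame(
        feature_id = fid,
        layer = unname(layer_of_kind[kind_of[members]]),
        log2fc = sign * effect,
        p_raw = runif(length(members), 1e-6, 1e-3),
        stringsAsFactors = FALSE
      )
    }
    if (n_null > 0L) {
      n_mapped <- round(null_fraction * n_null)
      pool <- setdiff(interactome$nodes$id, members)
      n_mapped <- min(n_mapped, length(pool))
      mapped_ids <- if (n_mapped > 0L) sample(pool, n_mapped) else character(0)
      free_ids <- if (n_null - n_mapped > 0L) {
        sprintf("null_%04d", seq_len(n_null - n_mapped))
      } else {
        character(0)
      }
      null_ids <- c(mapped_ids, free_ids)
      null_layer <- c(unname(layer_of_kind[kind_of[mapped_ids]]),
                      rep("protein", length(free_ids)))
      rows$null <- data.frame(
        feature_id = null_ids,
        layer = null_layer,
        log2fc = rnorm(length(null_ids), 0, 0.2),
        p_raw = runif(length(null_ids)),
        stringsAsFactors = FALSE
      )
    }
    out <- do.call(rbind, rows)
    if (is.null(out)) {
      out <- data.frame(feature_id = character(), layer = character(),
                        log2fc = numeric(), p_raw = numeric(),
                        stringsAsFactors = FALSE)
    }
    rownames(out) <- NULL
    out
  })
}

#' Generate a synthetic metabolite mass database
#'
#' Random monoisotopic masses uniform on (100, 900) Da for the given ids
#' (by default every metabolite-kind node of the interactome).
#'
#' @param interactome an `interactome`.
#' @param met_ids metabolite ids (default: all metabolite-kind nodes).
#' @param seed integer seed.
#' @return `data.frame` with `met_id`, `monoisotopic_mass`, `name`.
#' @export
generate_metabolite_db <- function(interactome,
                                   met_ids = NULL, seed = 1L) {
  if (is.null(met_ids)) {
    met_ids <- interactome$nodes$id[interactome$nodes$kind == "metabolite"]
  }
  with_seed(seed, {
    data.frame(met_id = met_ids,
               monoisotopic_mass = runif(length(met_ids), 100, 900),
               name = paste0("synthetic-", met_ids),
               stringsAsFactors = FALSE)
  })
}

#' Generate untargeted m/z peaks from planted metabolites
#'
#' Every planted metabolite (module member with a database mass) yields one
#' peak through a randomly chosen adduct, with multiplicative ppm error
#' `~ Normal(0, ppm_noise_sd)`.  Decoy peaks are rejection-sampled at m/z
#' values at least `5 * ppm_tol_ref` ppm away from every theoretical m/z of
#' the database, so they can never legitimately match.
#'
#' @param truth a `synthetic_truth`.
#' @param db metabolite database (see [generate_metabolite_db()]).
#' @param adducts adduct rules (default [default_adducts()]).
#' @param ppm_noise_sd mass-accuracy noise in ppm (default 2).
#' @param decoy_count number of decoy peaks (default 0).
#' @param ppm_tol_ref reference matching tolerance used to place decoys
#'   (default 10 ppm).
#' @param seed integer seed.
#' @return list with `peaks` (`peak_id`, `mz`, `mode`) and the updated
#'   `truth` whose `true_peak_matches` maps peak id -> met id.
#' @export
generate_peaks <- function(truth, db, adducts = default_adducts(),
                           ppm_noise_sd = 2, decoy_count = 0L,
                           ppm_tol_ref = 10, seed = 1L) {
  stopifnot(inherits(truth, "synthetic_truth"))
  planted <- intersect(names(truth$module_assignments), db$met_id)
  with_seed(seed, {
    peaks <- NULL
    matches <- character(0)
    if (length(planted) > 0L) {
      mass <- db$monoisotopic_mass[match(planted, db$met_id)]
      ai <- sample(nrow(adducts), length(planted), replace = TRUE)
      theo <- (mass + adducts$mass_shift[ai]) / adducts$charge[ai]
      mz <- theo * (1 + rnorm(length(planted), 0, ppm_noise_sd) * 1e-6)
      pid <- sprintf("peak_%04d", seq_along(planted))
      peaks <- data.frame(peak_id = pid, mz = mz,
                          mode = adducts$mode[ai], stringsAsFactors = FALSE)
      matches <- stats::setNames(planted, pid)
    }
    if (decoy_count > 0L) {
      all_theo <- unlist(lapply(seq_len(nrow(adducts)), function(i) {
        (db$monoisotopic_mass + adducts$mass_shift[i]) / adducts$charge[i]
      }))
      lo <- min(all_theo) * 0.9
      hi <- max(all_theo) * 1.1
      decoys <- numeric(0)
      tries <- 0L
      while (length(decoys) < decoy_count) {
        tries <- tries + 1L
        if (tries > 10000L) {
          stop_value("could not place %d decoy peaks away from the database",
                     decoy_count)
        }
        cand <- runif(1, lo, hi)
        ppm_dist <- min(abs(cand - all_theo) / all_theo * 1e6)
        if (ppm_dist >= 5 * ppm_tol_ref) decoys <- c(decoys, cand)
      }
      dmode <- sample(unique(adducts$mode), decoy_count, replace = TRUE)
      dpk <- data.frame(peak_id = sprintf("decoy_%04d", seq_len(decoy_count)),
                        mz = decoys, mode = dmode, stringsAsFactors = FALSE)
      peaks <- rbind(peaks, dpk)
    }
    if (is.null(peaks)) {
      peaks <- data.frame(peak_id = character(), mz = numeric(),
                          mode = character(), stringsAsFactors = FALSE)
    }
    truth$true_peak_matches <- matches
    truth$generation_config$ppm_noise_sd <- ppm_noise_sd
    truth$generation_config$decoy_count <- decoy_count
    list(peaks = peaks, truth = truth)
  })
}

#' Write a complete synthetic dataset in the pipeline's input formats
#'
#' Emits the edge TSV, differential TSV, peak and metabolite TSVs, an
#' adduct TSV, a GMT of planted modules as "true pathways", and a truth
#' JSON -- everything [run_pipeline()] needs.
#'
#' @param dir output directory (created).
#' @param n_nodes,attachment,kind_mix interactome parameters
#'   (see [generate_interactome()]).
#' @param n_modules,module_size module parameters (see [plant_modules()]).
#' @param effect_mu,effect_sd,n_null omics parameters
#'   (see [generate_omics()]).
#' @param decoy_count decoy peaks (see [generate_peaks()]).
#' @param seed master seed; stage seeds are derived by small offsets.
#' @return invisibly, a list with the generated objects and file paths.
#' @export
write_synthetic_dataset <- function(dir, n_nodes = 300L, attachment = 2L,
                                    kind_mix = c(protein = 0.70,
                                                 metabolite = 0.15,
                                                 phosphosite = 0.10,
                                                 tf = 0.05),
                                    n_modules = 1L, module_size = 12L,
                                    effect_mu = 2, effect_sd = 0.5,
                                    n_null = 100L, decoy_count = 10L,
                                    seed = 1L) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ix <- generate_interactome(n_nodes, attachment, kind_mix, seed = seed)
  truth <- plant_modules(ix, n_modules, module_size, seed = seed + 1L)
  db <- generate_metabolite_db(ix, seed = seed + 2L)
  pk <- generate_peaks(truth, db, decoy_count = decoy_count, seed = seed + 3L)
  truth <- pk$truth
  omics <- generate_omics(truth, ix, effect_mu, effect_sd,
                          n_null = n_null, seed = seed + 4L)

  edgelist <- interactome_edgelist(ix)
  edges_path <- file.path(dir, "edges.tsv")
  write.table(data.frame(source = edgelist$u, target = edgelist$v,
                         confidence = edgelist$confidence),
              edges_path, sep = "\t", quote = FALSE, row.names = FALSE)
  kinds_path <- file.path(dir, "node_kinds.tsv")
  write.table(ix$nodes[, c("id", "kind")], kinds_path, sep = "\t",
              quote = FALSE, row.names = FALSE)
  diff_path <- file.path(dir, "differential.tsv")
  write.table(omics, diff_path, sep = "\t", quote = FALSE, row.names = FALSE)
  peaks_path <- file.path(dir, "peaks.tsv")
  write.table(pk$peaks, peaks_path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  db_path <- file.path(dir, "metabolites.tsv")
  write.table(db, db_path, sep = "\t", quote = FALSE, row.names = FALSE)
  adducts_path <- file.path(dir, "adducts.tsv")
  write.table(default_adducts(), adducts_path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  gmt_path <- file.path(dir, "true_pathways.gmt")
  sets <- lapply(sort(unique(truth$module_assignments)), function(mod) {
    list(set_id = sprintf("planted_module_%d", mod),
         name = "planted ground-truth module",
         members = sort(names(truth$module_assignments)[
           truth$module_assignments == mod]))
  })
  write_gmt(sets, gmt_path)
  truth_path <- file.path(dir, "truth.json")
  jsonlite::write_json(
    list(module_assignments = as.list(truth$module_assignments),
         true_peak_matches = as.list(truth$true_peak_matches),
         generation_config = truth$generation_config),
    truth_path, auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  invisible(list(interactome = ix, truth = truth, db = db,
                 peaks = pk$peaks, omics = omics,
                 paths = list(edges = edges_path, node_kinds = kinds_path,
                              differential = diff_path, peaks = peaks_path,
                              metabolites = db_path, adducts = adducts_path,
                              gmt = gmt_path, truth = truth_path)))
}
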