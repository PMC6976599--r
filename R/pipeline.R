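#' Read and validate a pipeline run configuration
#'
#' The configuration is a YAML file (or an equivalent nested list) with the
#' blocks:
#'
#' \preformatted{
#' layers:            # one entry per interactome edge table
#'   - path: edges.tsv
#'     kind_u: protein
#'     kind_v: protein
#'     layer: synthetic
#' node_kinds: node_kinds.tsv   # optional id -> kind override table
#' differential: differential.tsv
#' peaks: peaks.tsv             # optional, with metabolites + adducts
#' metabolites: metabolites.tsv
#' adducts: adducts.tsv
#' gmt: true_pathways.gmt       # optional enrichment collection
#' outdir: out/
#' seed: 1
#' prizes: {alpha: 0.05, scale: 1}
#' pcsf: {beta: 1, omega: 1, mu: 0.005}
#' randomization: {n_runs: 100, sigma: 0.1,
#'                 min_robustness: 0.4, min_specificity: 0.4}
#' enrichment: {alpha: 0.05}
#' ppm_tol: 10
#' }
#'
#' Relative paths are resolved against the config file's directory.
#'
#' @param config path to a YAML file, or a list with the same structure.
#' @return validated config list (class `run_config`).
#' @export
read_run_config <- function(config) {
  base_dir <- "."
  if (is.character(config) && length(config) == 1L) {
    base_dir <- dirname(config)
    config <- yaml::read_yaml(config)
  }
  stopifnot(is.list(config))
  resolve <- function(p) {
    if (is.null(p)) return(NULL)
    if (file.exists(p)) p else file.path(base_dir, p)
  }
  if (is.null(config$layers) || length(config$layers) == 0L) {
    stop_value("config must list at least one interactome layer")
  }
  for (i in seq_along(config$layers)) {
    config$layers[[i]]$path <- resolve(config$layers[[i]]$path)
    if (!file.exists(config$layers[[i]]$path)) {
      stop_value("layer %d: input file '%s' does not exist",
                 i, config$layers[[i]]$path)
    }
  }
  for (key in c("node_kinds", "differential", "peaks", "metabolites",
                "adducts", "gmt")) {
    if (!is.null(config[[key]])) {
      config[[key]] <- resolve(config[[key]])
      if (!file.exists(config[[key]])) {
        stop_value("input file for '%s' does not exist: %s", key, config[[key]])
      }
    }
  }
  if (is.null(config$differential)) {
    stop_value("config must name a differential feature table")
  }
  if (is.null(config$outdir)) stop_value("config must name an output directory")
  config$seed <- as.integer(config$seed %||% 1L)
  config$ppm_tol <- config$ppm_tol %||% 10
  config$prizes <- utils::modifyList(list(alpha = 0.05, scale = 1),
                                     config$prizes %||% list())
  config$pcsf <- utils::modifyList(list(beta = 1, omega = 1, mu = 0.005,
                                        max_local_search_rounds = 20L),
                                   config$pcsf %||% list())
  config$randomization <- utils::modifyList(
    list(n_runs = 100L, sigma = 0.1,
         min_robustness = 0.4, min_specificity = 0.4),
    config$randomization %||% list()
  )
  rnd <- config$randomization
  if (rnd$n_runs < 1L) stop_value("n_runs must be >= 1")
  if (rnd$min_robustness < 0 || rnd$min_robustness > 1 ||
      rnd$min_specificity < 0 || rnd$min_specificity > 1) {
    stop_value("robustness/specificity thresholds must lie in [0, 1]")
  }
  config$enrichment <- utils::modifyList(list(alpha = 0.05),
                                         config$enrichment %||% list())
  class(config) <- c("run_config", "list")
  config
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop_value("pipeline stage '%s' failed: %s", name, conditionMessage(e))
  })
}

#' Run the full mode-of-action pipeline
#'
#' Stages: compose the interactome, match m/z peaks to metabolites (when
#' peak inputs are configured), derive prizes from the differential tables
#' (BH per layer, significance filter, `|log2fc|` prizes), solve the PCSF
#' instance, rerun under randomization for robustness/specificity scores,
#' filter the base solution at the configured thresholds, and enrich the
#' filtered network against the configured GMT collection.  Every
#' intermediate artifact is written under `outdir`; `manifest.json`
#' records the config echo, seeds, per-stage node/edge counts and stage
#' timings.  With a fixed seed, reruns are byte-identical except for the
#' timing fields.
#'
#' @param config a path to a YAML run configuration, or a list
#'   (see [read_run_config()]).
#' @return invisibly, a list with the composed interactome, prize table,
#'   base/filtered forests, score table, enrichment table and the manifest.
#' @export
run_pipeline <- function(config) {
  config <- read_run_config(config)
  outdir <- config$outdir
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  timings <- list()
  counts <- list()
  tick <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    res <- stage(name, expr)
    timings[[name]] <<- round(proc.time()[["elapsed"]] - t0, 3)
    res
  }

  kind_override <- NULL
  if (!is.null(config$node_kinds)) {
    kt <- read.delim(config$node_kinds, stringsAsFactors = FALSE)
    kind_override <- stats::setNames(kt$kind, kt$id)
  }
  edge_lists <- tick("load_layers", lapply(config$layers, function(ly) {
    e <- load_edge_table(ly$path, ly$kind_u %||% "protein",
                         ly$kind_v %||% "protein", ly$layer %||% "layer")
    if (!is.null(kind_override)) {
      ku <- kind_override[e$u]
      kv <- kind_override[e$v]
      e$kind_u <- ifelse(is.na(ku), e$kind_u, ku)
      e$kind_v <- ifelse(is.na(kv), e$kind_v, kv)
    }
    e
  }))

  if (!is.null(config$peaks)) {
    if (is.null(config$metabolites)) {
      stop_value("peak matching requires a metabolite database")
    }
    peak_edges <- tick("match_peaks", {
      peaks <- read.delim(config$peaks, stringsAsFactors = FALSE)
      db <- read.delim(config$metabolites, stringsAsFactors = FALSE)
      adducts <- if (is.null(config$adducts)) {
        default_adducts()
      } else {
        read.delim(config$adducts, stringsAsFactors = FALSE)
      }
      match_peaks(peaks, db, adducts, ppm_tol = config$ppm_tol)
    })
    counts$peak_metabolite_edges <- nrow(peak_edges)
    write.table(peak_edges, file.path(outdir, "peak_edges.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    if (nrow(peak_edges) > 0L) {
      edge_lists <- c(edge_lists,
                      list(peak_edges[, c("u", "v", "kind_u", "kind_v",
                                          "confidence", "cost", "layer")]))
    }
  }

  ix <- tick("compose", compose_interactome(edge_lists))
  counts$nodes <- nrow(ix$nodes)
  counts$edges <- nrow(ix$edges)
  write_interactome(ix, outdir)

  prizes <- tick("prizes", {
    feats <- load_differential_table(config$differential)
    feats <- adjust_differential(feats)
    sig <- suppressMessages(select_differential(feats, config$prizes$alpha))
    pt <- assign_prizes(sig, scale = config$prizes$scale)
    unmapped <- setdiff(pt$node_id, ix$nodes$id)
    if (length(unmapped) > 0L) {
      writeLines(unmapped, file.path(outdir, "unmapped_prizes.txt"))
    }
    pt
  })
  counts$prized_nodes <- nrow(prizes)
  write.table(prizes, file.path(outdir, "prizes.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)

  cfg <- pcsf_config(beta = config$pcsf$beta, omega = config$pcsf$omega,
                     mu = config$pcsf$mu, seed = config$seed,
                     max_local_search_rounds =
                       config$pcsf$max_local_search_rounds)
  rnd <- config$randomization
  rr <- tick("solve_randomize_filter", suppressMessages(
    run_randomization(ix, prizes, cfg,
                      n_runs = rnd$n_runs, sigma = rnd$sigma,
                      min_robustness = rnd$min_robustness,
                      min_specificity = rnd$min_specificity,
                      seed = config$seed)
  ))
  counts$base_nodes <- length(rr$base$nodes)
  counts$base_edges <- nrow(rr$base$edges)
  counts$filtered_nodes <- length(rr$filtered$nodes)
  counts$filtered_edges <- nrow(rr$filtered$edges)
  write_forest(rr$base, ix, prizes, outdir, prefix = "solution")
  write_forest(rr$filtered, ix, prizes, outdir, prefix = "filtered")
  keep_flag <- rr$scores$node_id %in% rr$filtered$nodes
  scores_out <- cbind(rr$scores, kept = keep_flag)
  write.table(scores_out, file.path(outdir, "node_scores.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)

  enrichment_tab <- NULL
  if (!is.null(config$gmt)) {
    enrichment_tab <- tick("enrich", {
      collection <- read_gmt(config$gmt)
      universe <- enrichment_universe(ix)
      nodes <- intersect(rr$filtered$nodes, universe)
      enrich(nodes, collection, universe, alpha = config$enrichment$alpha)
    })
    write.table(enrichment_tab, file.path(outdir, "enrichment.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
  }

  config_echo <- unclass(config)
  echo_path <- file.path(outdir, "config_echo.yaml")
  yaml::write_yaml(config_echo, echo_path)
  manifest <- list(
    config_hash = unname(tools::md5sum(echo_path)),
    seed = config$seed,
    objective = rr$base$objective,
    counts = counts,
    timings = timings
  )
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(interactome = ix, prizes = prizes, base = rr$base,
                 scores = rr$scores, filtered = rr$filtered,
                 enrichment = enrichment_tab, manifest = manifest,
                 outdir = outdir))
}
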