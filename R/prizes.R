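#' Benjamini-Hochberg adjustment
#'
#' Step-up FDR adjustment of raw p-values, capped at 1 and returned in the
#' input order.  Inputs must lie in (0, 1].
#'
#' @param p_values numeric vector of raw p-values in (0, 1].
#' @return adjusted p-values, same length and order.
#' @export
bh_adjust <- function(p_values) {
  check_prob_vector(p_values, "p_values")
  p.adjust(p_values, method = "BH")
}

#' Normalize a phosphosite log2 abundance to its parent protein
#'
#' Site-level changes are only interpretable once bulk protein changes are
#' removed; on the log2 scale that is a subtraction.
#'
#' @param phospho_log2,protein_log2 log2-scale abundances (vectorized).
#' @return `phospho_log2 - protein_log2`.
#' @export
normalize_phospho <- function(phospho_log2, protein_log2) {
  stopifnot(is.numeric(phospho_log2), is.numeric(protein_log2))
  phospho_log2 - protein_log2
}

#' Apply per-layer BH adjustment to a differential feature table
#'
#' @param features `data.frame` with columns `feature_id`, `layer`,
#'   `log2fc`, `p_raw`.
#' @return the table with a `p_adj` column filled per layer.
#' @export
adjust_differential <- function(features) {
  stopifnot(all(c("feature_id", "layer", "log2fc", "p_raw") %in% names(features)))
  if (nrow(features) == 0L) {
    features$p_adj <- numeric(0)
    return(features)
  }
  features$p_adj <- NA_real_
  for (lay in unique(features$layer)) {
    sel <- features$layer == lay
    features$p_adj[sel] <- bh_adjust(features$p_raw[sel])
  }
  features
}

#' Select significant differential features
#'
#' Keeps features with `p_adj` strictly below `alpha` (the boundary case
#' `p_adj == alpha` is dropped, so the decision is deterministic).
#'
#' @param features differential table with `p_adj` set (see
#'   [adjust_differential()]).
#' @param alpha significance threshold on the adjusted p-value
#'   (default 0.05).
#' @return the subset of significant rows.
#' @export
select_differential <- function(features, alpha = 0.05) {
  stopifnot(is.numeric(alpha), length(alpha) == 1L, alpha > 0, alpha <= 1)
  if (nrow(features) == 0L) return(features)
  if (is.null(features$p_adj) || anyNA(features$p_adj)) {
    stop_value("`p_adj` is unset: run adjust_differential() (BH per layer) first")
  }
  if (any(features$p_adj < features$p_raw - 1e-12)) {
    stop_value("p_adj smaller than p_raw: adjusted values are inconsistent")
  }
  kept <- features[features$p_adj < alpha, , drop = FALSE]
  counts <- table(factor(kept$layer, levels = unique(features$layer)))
  message(paste(sprintf("layer %s: kept %d", names(counts), counts),
                collapse = "; "))
  rownames(kept) <- NULL
  kept
}

#' Turn significant differential features into node prizes
#'
#' The default prize is `scale * |log2fc|` (the sign of the change carries
#' no information about how strongly a node should attract the network).
#' A `-log10(p_adj)` alternative is available.  A node measured in several
#' layers takes the maximum prize, so the same molecule is never
#' double-counted; provenance records every contributing layer.
#'
#' @param features significant features from [select_differential()].
#' @param scale positive prize scaling (default 1).
#' @param method `"abs_log2fc"` (default) or `"neglog10p"`.
#' @param mapping optional two-column `data.frame` (`feature_id`,
#'   `node_id`) unifying feature identifiers with interactome node ids;
#'   default is the identity mapping.
#' @return a `prize_table`: `data.frame` with columns `node_id`, `prize`,
#'   `layers`.
#' @export
assign_prizes <- function(features, scale = 1,
                          method = c("abs_log2fc", "neglog10p"),
                          mapping = NULL) {
  method <- match.arg(method)
  if (!is.numeric(scale) || length(scale) != 1L || scale <= 0) {
    stop_value("`scale` must be a single positive number")
  }
  if (nrow(features) == 0L) {
    out <- data.frame(node_id = character(), prize = numeric(),
                      layers = character(), stringsAsFactors = FALSE)
    class(out) <- c("prize_table", "data.frame")
    return(out)
  }
  node_id <- features$feature_id
  if (!is.null(mapping)) {
    stopifnot(all(c("feature_id", "node_id") %in% names(mapping)))
    m <- match(node_id, mapping$feature_id)
    node_id[!is.na(m)] <- mapping$node_id[m[!is.na(m)]]
  }
  raw <- switch(method,
    abs_log2fc = scale * abs(features$log2fc),
    neglog10p = scale * -log10(pmax(features$p_adj, 1e-300))
  )
  prize <- tapply(raw, node_id, max)
  layers <- tapply(features$layer, node_id,
                   function(l) paste(sort(unique(l)), collapse = ","))
  ids <- sort(unique(node_id))
  out <- data.frame(node_id = ids,
                    prize = unname(prize[ids]),
                    layers = unname(layers[ids]),
                    stringsAsFactors = FALSE)
  class(out) <- c("prize_table", "data.frame")
  out
}

#' Combine independent p-values with Fisher's method
#'
#' The statistic `-2 * sum(log(p_i))` follows a chi-square distribution on
#' `2k` degrees of freedom under the joint null; the combined p-value is
#' its upper tail.
#'
#' @param p_values independent p-values in (0, 1]; zero is rejected (the
#'   log is undefined) -- floor tiny p-values before calling.
#' @return combined p-value.
#' @examples
#' fisher_combine(c(0.05, 0.05, 0.05))
#' @export
fisher_combine <- function(p_values) {
  check_prob_vector(p_values, "p_values")
  stat <- -2 * sum(log(p_values))
  pchisq(stat, df = 2 * length(p_values), lower.tail = FALSE)
}

#' Read a differential feature TSV
#'
#' Expected columns: `feature_id`, `layer`, `log2fc`, `p_raw`, optionally
#' `p_adj`.
#' @param path TSV path.
#' @return `data.frame` of differential features.
#' @export
load_differential_table <- function(path) {
  tab <- read.delim(path, stringsAsFactors = FALSE)
  required <- c("feature_id", "layer", "log2fc", "p_raw")
  missing_cols <- setdiff(required, names(tab))
  if (length(missing_cols) > 0L) {
    stop_value("differential table '%s' is missing column(s): %s",
               path, paste(missing_cols, collapse = ", "))
  }
  check_prob_vector(tab$p_raw, sprintf("p_raw in '%s'", path))
  tab$feature_id <- as.character(tab$feature_id)
  tab
}
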