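#' Intersect two sets of genomic intervals
#'
#' Intervals are 0-based half-open (BED convention); abutting intervals do
#' not overlap.  Delegates to `GenomicRanges::intersect()` after
#' converting coordinates.
#'
#' @param a,b `data.frame`s with columns `chrom`, `start`, `end`.
#' @return `data.frame` of intersections in the same convention, sorted by
#'   `chrom`, `start`.
#' @export
overlap_intervals <- function(a, b) {
  check_intervals <- function(x, what) {
    stopifnot(all(c("chrom", "start", "end") %in% names(x)))
    if (nrow(x) == 0L) return(invisible(x))
    if (any(x$end <= x$start) || any(x$start < 0)) {
      bad <- which(x$end <= x$start | x$start < 0)[1L]
      stop_value("malformed interval in %s at row %d: [%d, %d)",
                 what, bad, x$start[bad], x$end[bad])
    }
    invisible(x)
  }
  check_intervals(a, "a")
  check_intervals(b, "b")
  if (nrow(a) == 0L || nrow(b) == 0L) {
    return(data.frame(chrom = character(), start = integer(),
                      end = integer(), stringsAsFactors = FALSE))
  }
  to_gr <- function(x) {
    GenomicRanges::GRanges(x$chrom, IRanges::IRanges(x$start + 1L, x$end))
  }
  ov <- suppressWarnings(GenomicRanges::intersect(to_gr(a), to_gr(b)))
  out <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(ov)),
    start = GenomicRanges::start(ov) - 1L,
    end = GenomicRanges::end(ov),
    stringsAsFactors = FALSE
  )
  out <- out[order(out$chrom, out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Read a BED file of genomic intervals
#'
#' Only the first three (or four, if a name column exists) columns are
#' used; coordinates stay 0-based half-open.
#' @param path BED path.
#' @return `data.frame` with `chrom`, `start`, `end` and optionally `name`.
#' @export
read_bed <- function(path) {
  tab <- read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(tab) < 3L) stop_value("BED file '%s' has fewer than 3 columns", path)
  out <- data.frame(chrom = as.character(tab[[1L]]),
                    start = as.integer(tab[[2L]]),
                    end = as.integer(tab[[3L]]),
                    stringsAsFactors = FALSE)
  if (ncol(tab) >= 4L) out$name <- as.character(tab[[4L]])
  out
}

#' Construct a position weight matrix object
#'
#' @param motif_id motif identifier.
#' @param tf_name transcription factor name.
#' @param matrix 4 x L matrix of per-position base probabilities, rows in
#'   A, C, G, T order; every column must sum to 1 (tolerance 1e-6).
#' @return a `pwm` object.
#' @export
pwm <- function(motif_id, tf_name, matrix) {
  matrix <- as.matrix(matrix)
  if (nrow(matrix) != 4L || ncol(matrix) < 1L) {
    stop_value("PWM matrix must be 4 x L with L >= 1")
  }
  if (any(matrix < 0) || any(abs(colSums(matrix) - 1) > 1e-6)) {
    stop_value("PWM '%s': every column must be nonnegative and sum to 1",
               motif_id)
  }
  rownames(matrix) <- c("A", "C", "G", "T")
  structure(list(motif_id = motif_id, tf_name = tf_name, matrix = matrix),
            class = "pwm")
}

#' Read PWMs from a JASPAR-style tab matrix file
#'
#' Format: a header line `>motif_id tf_name` followed by four lines of
#' whitespace-separated counts or probabilities (A, C, G, T order,
#' optionally prefixed with the base letter).  Counts are normalized per
#' column.
#' @param path file path.
#' @return list of `pwm` objects.
#' @export
read_pwms <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  starts <- grep("^>", lines)
  if (length(starts) == 0L) stop_value("no '>' motif headers in '%s'", path)
  lapply(seq_along(starts), function(i) {
    from <- starts[i]
    header <- strsplit(sub("^>", "", lines[from]), "\\s+")[[1L]]
    motif_id <- header[1L]
    tf_name <- if (length(header) > 1L) header[2L] else header[1L]
    rows <- lines[(from + 1L):(from + 4L)]
    vals <- lapply(rows, function(r) {
      r <- gsub("^\\s*[ACGTacgt]\\s*\\[?", "", r)
      r <- gsub("\\]\\s*$", "", r)
      as.numeric(strsplit(trimws(r), "\\s+")[[1L]])
    })
    if (length(unique(lengths(vals))) != 1L) {
      stop_value("motif '%s': rows have unequal lengths", motif_id)
    }
    mat <- do.call(rbind, vals)
    mat <- sweep(mat, 2L, colSums(mat), "/")
    pwm(motif_id, tf_name, mat)
  })
}

#' Scan a DNA sequence with a PWM
#'
#' Both strands are scanned; windows containing `N` are skipped.  Scores
#' are log2 odds in bits against the background, with a pseudocount added
#' to the PWM probabilities so zero-probability entries stay finite.  A
#' window is a hit when its score reaches `threshold_bits`.
#'
#' @param sequence a DNA string over A, C, G, T, N.
#' @param pwm a `pwm` object.
#' @param background length-4 base composition (A, C, G, T), summing to 1.
#' @param threshold_bits minimum log2-odds score for a hit.
#' @param pseudocount probability pseudocount (default 0.01).
#' @return `data.frame` of hits: `motif_id`, `start` (0-based), `end`,
#'   `score`, `strand`.
#' @export
scan_pwm <- function(sequence, pwm, background = rep(0.25, 4),
                     threshold_bits, pseudocount = 0.01) {
  stopifnot(inherits(pwm, "pwm"))
  if (abs(sum(background) - 1) > 1e-6 || any(background <= 0)) {
    stop_value("background must be positive and sum to 1")
  }
  M <- pwm$matrix
  L <- ncol(M)
  q <- (M + pseudocount) / (1 + 4 * pseudocount)
  lod <- log2(q / background)  # 4 x L

  score_strand <- function(seq_chars) {
    n <- length(seq_chars)
    if (n < L) return(NULL)
    code <- match(seq_chars, c("A", "C", "G", "T"))  # N -> NA
    n_win <- n - L + 1L
    sc <- numeric(n_win)
    ok <- rep(TRUE, n_win)
    for (j in seq_len(L)) {
      idx <- code[j:(j + n_win - 1L)]
      bad <- is.na(idx)
      ok <- ok & !bad
      idx[bad] <- 1L
      sc <- sc + lod[cbind(idx, j)]
    }
    list(score = sc, ok = ok)
  }

  chars <- strsplit(toupper(sequence), "")[[1L]]
  bad_chars <- setdiff(unique(chars), c("A", "C", "G", "T", "N"))
  if (length(bad_chars) > 0L) {
    stop_value("sequence contains invalid character '%s'", bad_chars[1L])
  }
  n <- length(chars)
  hits <- list()
  fwd <- score_strand(chars)
  if (!is.null(fwd)) {
    sel <- which(fwd$ok & fwd$score >= threshold_bits)
    if (length(sel) > 0L) {
      hits[["+"]] <- data.frame(motif_id = pwm$motif_id,
                                start = sel - 1L, end = sel - 1L + L,
                                score = fwd$score[sel], strand = "+",
                                stringsAsFactors = FALSE)
    }
  }
  comp <- chartr("ACGTN", "TGCAN", chars)
  rc <- rev(comp)
  rev_hits <- score_strand(rc)
  if (!is.null(rev_hits)) {
    sel <- which(rev_hits$ok & rev_hits$score >= threshold_bits)
    if (length(sel) > 0L) {
      # window i (1-based) on the reverse complement maps to
      # [n - i + 1 - L, n - i + 1) on the forward strand, 0-based
      start0 <- n - (sel - 1L) - L
      hits[["-"]] <- data.frame(motif_id = pwm$motif_id,
                                start = start0, end = start0 + L,
                                score = rev_hits$score[sel], strand = "-",
                                stringsAsFactors = FALSE)
    }
  }
  if (length(hits) == 0L) {
    return(data.frame(motif_id = character(), start = integer(),
                      end = integer(), score = numeric(),
                      strand = character(), stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, hits)
  out <- out[order(out$start, out$strand), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Read promoter sequences from a FASTA file
#'
#' Sequence names are truncated at the first whitespace so they match gene
#' ids in promoter BED tables.
#' @param path FASTA path.
#' @return named character vector of sequences.
#' @export
read_promoter_fasta <- function(path) {
  seqs <- Biostrings::readDNAStringSet(path)
  stats::setNames(as.character(seqs), sub("\\s.*$", "", names(seqs)))
}

#' Motif enrichment of foreground promoters against a background universe
#'
#' Tests whether motif-bearing promoters are over-represented among the
#' foreground promoters, by the hypergeometric upper tail over the
#' background universe, with a Haldane-corrected odds ratio.
#'
#' @param hits_fg number of motif-bearing promoters in the foreground.
#' @param promoters_fg number of foreground promoters.
#' @param hits_bg number of motif-bearing promoters in the background
#'   universe.
#' @param promoters_bg number of promoters in the background universe.
#' @return list with `odds_ratio` and `p`.
#' @export
motif_enrichment <- function(hits_fg, promoters_fg, hits_bg, promoters_bg) {
  if (hits_fg > promoters_fg || hits_bg > promoters_bg ||
      promoters_fg > promoters_bg || hits_fg > hits_bg) {
    stop_value("inconsistent motif counts: fg %d/%d, bg %d/%d",
               hits_fg, promoters_fg, hits_bg, promoters_bg)
  }
  p <- hypergeom_tail(hits_fg, hits_bg, promoters_fg, promoters_bg)
  a <- hits_fg
  b <- promoters_fg - hits_fg
  cc <- hits_bg - hits_fg
  d <- (promoters_bg - promoters_fg) - cc
  if (min(a, b, cc, d) == 0L) {
    a <- a + 0.5; b <- b + 0.5; cc <- cc + 0.5; d <- d + 0.5
  }
  list(odds_ratio = (a * d) / (b * cc), p = p)
}

#' Predict transcriptional regulators from DE genes and accessible promoters
#'
#' The foreground is the promoters of differentially expressed genes that
#' intersect H3K4me3 regions (accessible chromatin); the background is all
#' H3K4me3-intersected promoters.  Each PWM is scanned over the promoter
#' sequences; TFs whose motif-bearing promoters are enriched in the
#' foreground (BH-adjusted hypergeometric p < `alpha`) are emitted as
#' predicted regulators with prize `-log10(p_adj)`, capped.
#'
#' @param de_genes character vector of differentially expressed gene ids.
#' @param promoters `data.frame` with `chrom`, `start`, `end`, `name`
#'   (gene id), 0-based half-open; typically TSS +/- 2 kb windows.
#' @param h3k4me3 `data.frame` of H3K4me3 intervals (`chrom`, `start`,
#'   `end`).
#' @param sequences named character vector (or `Biostrings::DNAStringSet`)
#'   of promoter sequences keyed by gene id.
#' @param pwms list of `pwm` objects.
#' @param threshold_bits PWM hit threshold in bits (default 7).
#' @param background base composition for scanning.
#' @param alpha significance level on the adjusted p (default 0.05).
#' @param prize_cap cap on the TF prize (default 10).
#' @return `data.frame` with one row per PWM: `motif_id`, `tf_name`,
#'   `hits_fg`, `hits_bg`, `odds_ratio`, `p`, `p_adj`, `significant`,
#'   `prize`.
#' @export
predict_tfs <- function(de_genes, promoters, h3k4me3, sequences, pwms,
                        threshold_bits = 7, background = rep(0.25, 4),
                        alpha = 0.05, prize_cap = 10) {
  if (inherits(sequences, "DNAStringSet")) {
    sequences <- stats::setNames(as.character(sequences), names(sequences))
  }
  stopifnot(!is.null(names(sequences)), "name" %in% names(promoters))
  # promoters overlapping any H3K4me3 interval form the accessible universe
  accessible <- vapply(seq_len(nrow(promoters)), function(i) {
    nrow(overlap_intervals(promoters[i, , drop = FALSE], h3k4me3)) > 0L
  }, TRUE)
  universe_genes <- promoters$name[accessible]
  universe_genes <- intersect(universe_genes, names(sequences))
  fg_genes <- intersect(universe_genes, de_genes)
  if (length(universe_genes) == 0L) {
    stop_value("no promoter overlaps the H3K4me3 regions")
  }
  rows <- lapply(pwms, function(pw) {
    has_hit <- vapply(universe_genes, function(g) {
      nrow(scan_pwm(sequences[[g]], pw, background, threshold_bits)) > 0L
    }, TRUE)
    hits_bg <- sum(has_hit)
    hits_fg <- sum(has_hit[universe_genes %in% fg_genes])
    me <- motif_enrichment(hits_fg, length(fg_genes), hits_bg,
                           length(universe_genes))
    data.frame(motif_id = pw$motif_id, tf_name = pw$tf_name,
               hits_fg = hits_fg, hits_bg = hits_bg,
               odds_ratio = me$odds_ratio, p = me$p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_adj <- p.adjust(out$p, method = "BH")
  out$significant <- out$p_adj < alpha
  out$prize <- ifelse(out$significant,
                      pmin(-log10(pmax(out$p_adj, 1e-300)), prize_cap), 0)
  out <- out[order(out$p_adj, out$motif_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}
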