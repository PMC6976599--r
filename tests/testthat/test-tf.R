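iv <- function(chrom, start, end) {
  data.frame(chrom = chrom, start = start, end = end,
             stringsAsFactors = FALSE)
}

test_that("interval intersection uses half-open semantics", {
  expect_equal(overlap_intervals(iv("chr1", 0, 100), iv("chr1", 50, 150)),
               iv("chr1", 50L, 100L))
  expect_equal(nrow(overlap_intervals(iv("chr1", 0, 100),
                                      iv("chr1", 100, 200))), 0L)
  a <- iv("chr1", 10, 40)
  expect_equal(overlap_intervals(a, a), iv("chr1", 10L, 40L))
  # commutative, chromosome-aware
  b <- iv(c("chr1", "chr2"), c(0, 5), c(20, 25))
  expect_equal(overlap_intervals(a, b), overlap_intervals(b, a))
  expect_equal(nrow(overlap_intervals(iv("chr3", 0, 10), a)), 0L)
  expect_error(overlap_intervals(iv("chr1", 10, 10), a), "malformed")
})

test_that("PWM construction validates probability columns", {
  m <- matrix(c(1, 0, 0, 0), nrow = 4)
  pw <- pwm("m1", "TF1", m)
  expect_equal(ncol(pw$matrix), 1L)
  expect_error(pwm("m1", "TF1", matrix(c(0.5, 0.2, 0.2, 0.2), 4)), "sum to 1")
  expect_error(pwm("m1", "TF1", matrix(1, 1, 1)), "4 x L")
  expect_error(scan_pwm("ACGT", pw, background = c(0.5, 0.5, 0, 0),
                        threshold_bits = 1), "background")
})

test_that("scanning scores log2 odds on both strands and skips N", {
  pw <- pwm("mA", "TFA", matrix(c(1, 0, 0, 0), nrow = 4))
  # single A against uniform background: about log2(4) bits (pseudocounted)
  hits <- scan_pwm("A", pw, threshold_bits = 1)
  expect_equal(nrow(hits), 1L)
  expect_equal(hits$score, log2((1.01 / 1.04) / 0.25), tolerance = 1e-12)
  expect_gt(hits$score, 1.9)

  # "C": no + strand hit; - strand reads "G", also no hit
  expect_equal(nrow(scan_pwm("C", pw, threshold_bits = 1)), 0L)

  # N positions are skipped: "ANA" hits at offsets 0 and 2 only (+ strand)
  hits3 <- scan_pwm("ANA", pw, threshold_bits = 1)
  expect_equal(sort(hits3$start[hits3$strand == "+"]), c(0L, 2L))

  # a - strand hit maps back to forward coordinates: motif AC on "GT"
  pw2 <- pwm("mAC", "TFB",
             matrix(c(1, 0, 0, 0, 0, 1, 0, 0), nrow = 4))
  rev_hits <- scan_pwm("GGT", pw2, threshold_bits = 2)
  expect_equal(rev_hits$strand, "-")
  expect_equal(rev_hits$start, 1L)
  expect_equal(rev_hits$end, 3L)
  expect_error(scan_pwm("AXA", pw, threshold_bits = 1), "invalid")
})

test_that("reverse-complementing sequences preserves the hit score multiset", {
  revcomp <- function(s) {
    paste(rev(strsplit(chartr("ACGTN", "TGCAN", s), "")[[1]]), collapse = "")
  }
  withr::with_seed(41, {
    pw <- pwm("mr", "TFR", {
      m <- matrix(runif(4 * 5), 4)
      sweep(m, 2, colSums(m), "/")
    })
    for (i in 1:20) {
      s <- paste(sample(c("A", "C", "G", "T", "N"), 30, TRUE,
                        prob = c(0.24, 0.24, 0.24, 0.24, 0.04)),
                 collapse = "")
      h1 <- scan_pwm(s, pw, threshold_bits = -5)
      h2 <- scan_pwm(revcomp(s), pw, threshold_bits = -5)
      expect_equal(sort(h1$score), sort(h2$score), tolerance = 1e-9)
    }
  })
})

test_that("motif enrichment equals exact enumeration and flags edge cases", {
  me <- motif_enrichment(4, 5, 4, 10)
  expect_equal(me$p, 6 / 252)
  expect_equal(motif_enrichment(0, 5, 4, 10)$p, 1)         # k = 0
  expect_equal(motif_enrichment(4, 10, 4, 10)$p, 1)        # fg = universe
  expect_error(motif_enrichment(6, 5, 6, 10), "inconsistent")
  # against enumeration on small universes
  for (case in list(c(2, 4, 5, 12), c(1, 3, 6, 9), c(3, 3, 4, 8))) {
    expect_equal(motif_enrichment(case[1], case[2], case[3], case[4])$p,
                 oracle_hyper_tail(case[1], case[3], case[2], case[4]),
                 tolerance = 1e-12)
  }
})

test_that("promoter FASTA files read into named sequences", {
  path <- tempfile(fileext = ".fa")
  writeLines(c(">g01 chr1:0-7", "TTACGTT", ">g02", "AAAA"), path)
  seqs <- read_promoter_fasta(path)
  expect_equal(names(seqs), c("g01", "g02"))
  expect_equal(unname(seqs["g01"]), "TTACGTT")
  hits <- scan_pwm(seqs[["g01"]],
                   pwm("mAC", "ACF",
                       matrix(c(1, 0, 0, 0, 0, 1, 0, 0), nrow = 4)),
                   threshold_bits = 3)
  # AC at offset 2 (+) and its reverse complement GT at offset 4 (-)
  expect_equal(hits$start[hits$strand == "+"], 2L)
  expect_equal(hits$start[hits$strand == "-"], 4L)
})

test_that("JASPAR-style PWM files parse and normalize", {
  path <- tempfile(fileext = ".pwm")
  writeLines(c(
    ">M001 TFX",
    "A [ 8 0 ]",
    "C [ 0 8 ]",
    "G [ 0 0 ]",
    "T [ 0 0 ]",
    ">M002 TFY",
    "4 0", "0 0", "0 4", "0 0"
  ), path)
  pwms <- read_pwms(path)
  expect_length(pwms, 2L)
  expect_equal(pwms[[1]]$tf_name, "TFX")
  expect_equal(pwms[[1]]$matrix[, 1], c(A = 1, C = 0, G = 0, T = 0))
  expect_equal(pwms[[2]]$matrix[, 1], c(A = 1, C = 0, G = 0, T = 0))
})

test_that("TF prediction flags the regulator of the DE foreground", {
  # 12 promoters; the first six are DE and carry the AC motif, the other
  # six do not; all overlap the accessible regions
  genes <- sprintf("g%02d", 1:12)
  promoters <- data.frame(chrom = "chr1",
                          start = seq(0, by = 100, length.out = 12),
                          end = seq(50, by = 100, length.out = 12),
                          name = genes, stringsAsFactors = FALSE)
  h3k <- iv("chr1", 0, 2000)
  seqs <- stats::setNames(
    c(rep("TTACGTT", 6), rep("TTTTTTT", 6)), genes
  )
  pwm_ac <- pwm("mAC", "ACF",
                matrix(c(1, 0, 0, 0, 0, 1, 0, 0), nrow = 4))
  pwm_gg <- pwm("mGG", "GGF",
                matrix(c(0, 0, 1, 0, 0, 0, 1, 0), nrow = 4))
  out <- predict_tfs(genes[1:6], promoters, h3k, seqs,
                     list(pwm_ac, pwm_gg), threshold_bits = 3)
  expect_equal(out$hits_bg[out$motif_id == "mAC"], 6L)
  expect_equal(out$hits_fg[out$motif_id == "mAC"], 6L)
  expect_true(out$significant[out$motif_id == "mAC"])
  expect_false(out$significant[out$motif_id == "mGG"])
  expect_gt(out$prize[out$motif_id == "mAC"], 0)
  expect_equal(out$prize[out$motif_id == "mGG"], 0)
})
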