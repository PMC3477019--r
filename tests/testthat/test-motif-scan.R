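test_that("information values hit the closed-form anchors", {
  p_uniform <- fabricated_pwm(matrix(0.25, 4, 1), ci = NA)
  # via build_pwm: uniform counts -> Ci = 0
  p <- build_pwm(counts = matrix(c(1, 1, 1, 1), 4, 1,
                                 dimnames = list(c("A", "C", "G", "T"))),
                 core_length = 1)
  expect_equal(p$ci, 0)
  # single base -> Ci = 100
  p1 <- build_pwm(counts = matrix(c(8, 0, 0, 0), 4, 1,
                                  dimnames = list(c("A", "C", "G", "T"))),
                  core_length = 1)
  expect_equal(p1$ci, 100)
  # two equiprobable bases -> (100 / ln 4)(ln 4 - ln 2) = 50
  p2 <- build_pwm(counts = matrix(c(4, 4, 0, 0), 4, 1,
                                  dimnames = list(c("A", "C", "G", "T"))),
                  core_length = 1)
  expect_equal(p2$ci, 50, tolerance = 1e-12)
})

test_that("build_pwm frequencies, pseudocounts and core placement", {
  p <- build_pwm(sites = c("ACGT", "ACGA", "ACTT"))
  expect_equal(colSums(p$freq), rep(1, 4))
  expect_equal(unname(p$freq["A", 1]), 1)
  expect_equal(unname(p$freq["T", 4]), 2 / 3)
  # pseudocount: (count + pc) / (n + 4 pc)
  pp <- build_pwm(sites = c("A", "A"), pseudocount = 1, core_length = 1)
  expect_equal(unname(pp$freq["A", 1]), 3 / 6)
  expect_equal(unname(pp$freq["C", 1]), 1 / 6)
  expect_error(build_pwm(sites = c("ACG", "AC")), "equal length")
  expect_error(build_pwm(counts = matrix(0, 4, 2)), "all-zero")
  # core = most informative consecutive window, leftmost on ties
  counts <- rbind(A = c(9, 9, 3, 9, 9, 3), C = c(0, 0, 3, 0, 0, 3),
                  G = c(0, 0, 3, 0, 0, 3), T = c(0, 0, 0, 0, 0, 0))
  pc <- build_pwm(counts = counts, core_length = 2)
  expect_equal(pc$core_start, 1L)  # ties between windows 1-2 and 4-5
})

test_that("score_window implements the information-weighted ratio", {
  # fabricated matrix reproducing a hand evaluation:
  # Ci = (100, 50), f(1, consensus) = 0.9, f(2, consensus) = 0.8,
  # window hits consensus at pos 1 and a f = 0.2 base at pos 2
  freq <- matrix(c(0.9, 0.05, 0.03, 0.02,
                   0.8, 0.2, 0.0, 0.0), 4, 2)
  fp <- fabricated_pwm(freq, ci = c(100, 50))
  expect_equal(score_window(fp, "AC"),
               (100 * 0.9 + 50 * 0.2) / (100 * 0.9 + 50 * 0.8),
               tolerance = 1e-12)
  expect_equal(round(score_window(fp, "AC"), 3), 0.769)
  expect_error(score_window(fp, "ACG"), "length")
})

test_that("consensus scores 1.0 and zero-information positions cannot penalize", {
  for (seed in 1:5) {
    set.seed(seed)
    sites <- vapply(1:8, function(i) random_seq(10), character(1))
    p <- build_pwm(sites = sites, pseudocount = 0.25)
    cons <- pwm_consensus(p)
    expect_equal(score_window(p, cons), 1)
    expect_equal(score_window(p, cons, part = "core"), 1)
  }
  # a window differing only at a Ci = 0 position still scores 1
  counts <- rbind(A = c(8, 2), C = c(0, 2), G = c(0, 2), T = c(0, 2))
  p <- build_pwm(counts = counts, core_length = 1)
  expect_equal(p$ci[2], 0)
  expect_equal(score_window(p, "AC"), score_window(p, "AA"))
  expect_equal(score_window(p, "AC"), 1)
})

test_that("scan_pwm finds a planted consensus once, on the right strand", {
  p <- toy_pwm()
  cons <- pwm_consensus(p)
  set.seed(4)
  bg <- paste0(strrep("C", 30), cons, strrep("C", 30))
  hits <- scan_pwm(setNames(bg, "s"), p, 0.95, 0.95)
  expect_equal(nrow(hits), 1L)
  expect_equal(hits$strand, "+")
  expect_equal(hits$start, 30L)
  expect_equal(hits$matrix_similarity, 1)
  expect_equal(hits$core_similarity, 1)
  # reverse-complemented sequence: same hit on -, mirrored coordinates
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(bg)))
  hits2 <- scan_pwm(setNames(rc, "s"), p, 0.95, 0.95)
  expect_equal(nrow(hits2), 1L)
  expect_equal(hits2$strand, "-")
  expect_equal(hits2$start, unname(nchar(bg)) - hits$end)
})

test_that("scan_pwm equals brute-force window scoring and is threshold-monotone", {
  p <- toy_pwm()
  brute <- function(s, id, cth, mth) {
    n <- nchar(s)
    L <- p$length
    rows <- list()
    for (strand in c("+", "-")) {
      str <- if (strand == "+") s else
        as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
      for (off in 0:(n - L)) {
        w <- substr(str, off + 1, off + L)
        cs <- score_window(p, w, "core")
        ms <- score_window(p, w, "matrix")
        if (cs >= cth && ms >= mth) {
          start <- if (strand == "+") off else n - (off + L)
          rows[[length(rows) + 1]] <- tibble::tibble(
            motif = p$name, sequence_id = id, start = start,
            end = start + L, strand = strand,
            core_similarity = cs, matrix_similarity = ms
          )
        }
      }
    }
    out <- dplyr::bind_rows(rows)
    if (nrow(out) == 0) return(out)
    dplyr::arrange(out, start, strand)
  }
  set.seed(11)
  for (i in 1:10) {
    s <- random_seq(150)
    cth <- runif(1, 0.3, 0.9)
    mth <- runif(1, 0.3, 0.9)
    got <- scan_pwm(setNames(s, "x"), p, cth, mth)
    want <- brute(s, "x", cth, mth)
    expect_equal(nrow(got), nrow(want))
    if (nrow(got) > 0) {
      expect_equal(got$start, as.integer(want$start))
      expect_equal(got$strand, want$strand)
      expect_equal(got$matrix_similarity, want$matrix_similarity,
                   tolerance = 1e-12)
    }
    # monotonicity: lowering thresholds never removes hits
    more <- scan_pwm(setNames(s, "x"), p, cth * 0.8, mth * 0.8)
    key <- function(h) paste(h$start, h$strand)
    expect_true(all(key(got) %in% key(more)))
  }
})

test_that("IUPAC degeneracy, mismatches and strand handling", {
  # R matches A or G
  expect_equal(nrow(scan_iupac(c(s = "GAT"), iupac_motif("m", "RAT"))), 1L)
  expect_equal(nrow(scan_iupac(c(s = "AAT"), iupac_motif("m", "RAT"),
                               strands = "forward")), 1L)
  expect_equal(nrow(scan_iupac(c(s = "CAT"), iupac_motif("m", "RAT"),
                               strands = "forward")), 0L)
  # GRBOX planted at offset 7
  s <- paste0("ACGACGA", "CATTGTT", "GGG")
  h <- scan_iupac(setNames(s, "s"), iupac_motif("GRBOX", "CATTGTT"))
  h <- h[h$strand == "+", ]
  expect_equal(h$start, 7L)
  expect_equal(h$matrix_similarity, 1)
  # TTATA contains TATAA only as reverse complement
  h2 <- scan_iupac(c(s = "GGTTATAGG"), iupac_motif("t", "TATAA"))
  expect_equal(h2$strand, "-")
  # mismatch allowance
  h3 <- scan_iupac(c(s = "CATTGAT"), iupac_motif("g", "CATTGTT", 1),
                   strands = "forward")
  expect_equal(h3$matrix_similarity, 6 / 7)
  expect_equal(nrow(scan_iupac(c(s = "CATTGAT"),
                               iupac_motif("g", "CATTGTT", 0),
                               strands = "forward")), 0L)
  # sequence N never satisfies a non-N pattern symbol
  expect_equal(nrow(scan_iupac(c(s = "CNT"), iupac_motif("m", "CAT"),
                               strands = "forward")), 0L)
  expect_equal(nrow(scan_iupac(c(s = "CNT"), iupac_motif("m", "CNT"),
                               strands = "forward")), 1L)
  expect_error(iupac_motif("bad", "ACGU"), "illegal")
})

test_that("strand involution: scanning the reverse complement mirrors hits", {
  p <- toy_pwm()
  m <- iupac_motif("g", "CATTGDT", 1)
  set.seed(21)
  for (i in 1:5) {
    s <- random_seq(200)
    rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
    n <- nchar(s)
    for (scan in list(
      function(x) scan_pwm(setNames(x, "s"), p, 0.5, 0.5),
      function(x) scan_iupac(setNames(x, "s"), m)
    )) {
      h1 <- scan(s)
      h2 <- scan(rc)
      k1 <- sort(paste(h1$start, h1$strand))
      k2 <- sort(paste(n - h2$end, ifelse(h2$strand == "+", "-", "+")))
      expect_identical(k1, k2)
    }
  }
})

test_that("PWM library and IUPAC list files round-trip", {
  lib <- list(`V$TOY.01` = toy_pwm())
  path <- withr::local_tempfile(fileext = ".tsv")
  write_pwm_library(lib, path)
  back <- read_pwm_library(path)
  expect_equal(names(back), "V$TOY.01")
  expect_equal(back[["V$TOY.01"]]$freq, lib[["V$TOY.01"]]$freq,
               tolerance = 1e-6)
  expect_equal(back[["V$TOY.01"]]$family, "V$TOY")

  mpath <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("GRBOX\tCATTGTT\t0", "TATA\tTATAA\t1"), mpath)
  motifs <- read_iupac_motifs(mpath)
  expect_equal(motifs$TATA$max_mismatches, 1L)
  expect_equal(motifs$GRBOX$pattern, "CATTGTT")
})

test_that("tidy and glance summarize a PWM", {
  p <- toy_pwm()
  td <- tidy(p)
  expect_equal(nrow(td), 4 * p$length)
  expect_equal(sum(td$frequency), p$length)
  g <- glance(p)
  expect_equal(g$length, p$length)
  expect_equal(g$consensus, pwm_consensus(p))
})
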