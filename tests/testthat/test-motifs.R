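# Motif reading, PWM scanning, enrichment statistics, BH adjustment,
# GC matching.

test_that("read_motifs parses JASPAR counts with pseudocount", {
  f <- withr::local_tempfile(fileext = ".jaspar")
  writeLines(c(">M1 testmotif",
               "A [ 8 0 2 2 ]",
               "C [ 0 8 2 2 ]",
               "G [ 0 0 2 2 ]",
               "T [ 0 0 2 2 ]"), f)
  m <- read_motifs(f, pseudocount = 0.25)
  expect_length(m, 1)
  # (8 + 0.25) / (8 + 1) per the pseudocount rule
  expect_equal(unname(m[[1]]$matrix["A", 1]), 8.25 / 9, tolerance = 1e-3)
  expect_equal(unname(m[[1]]$matrix["C", 1]), 0.25 / 9, tolerance = 1e-3)
  expect_equal(unname(m[[1]]$matrix[, 3]), rep(0.25, 4))
  expect_equal(colSums(m[[1]]$matrix), rep(1, 4), ignore_attr = TRUE)

  writeLines(c(">M2 bad", "A [ 0 0 ]", "C [ 0 0 ]", "G [ 0 0 ]",
               "T [ 0 0 ]"), f)
  expect_error(read_motifs(f), "non-positive")
  writeLines(character(), f)
  expect_error(read_motifs(f), "no motif records")
})

test_that("read_motifs parses HOMER-style probability rows", {
  f <- withr::local_tempfile(fileext = ".motif")
  writeLines(c(">ACGTA\tM3_homer\t6.5",
               "0.97\t0.01\t0.01\t0.01",
               "0.01\t0.97\t0.01\t0.01",
               "0.01\t0.01\t0.97\t0.01",
               "0.01\t0.01\t0.01\t0.97",
               "0.97\t0.01\t0.01\t0.01"), f)
  m <- read_motifs(f)
  expect_equal(m[[1]]$name, "M3_homer")
  expect_equal(ncol(m[[1]]$matrix), 5)
  expect_equal(pwm_consensus(m[[1]]), "ACGTA")
  expect_equal(colSums(m[[1]]$matrix), rep(1, 5), ignore_attr = TRUE)
})

test_that("scan_sequence finds the consensus at full score", {
  m <- default_motifs()[["KLF_like_synthetic"]]
  cons <- pwm_consensus(m)
  hits <- scan_sequence(m, cons, threshold_frac = 1)
  expect_equal(hits$offset, 0)
  expect_equal(hits$strand, "+")
  expect_equal(hits$score, flowreg:::pwm_max_score(m), tolerance = 1e-9)
  # all-N sequence yields no hits
  expect_equal(nrow(scan_sequence(m, strrep("N", 50))), 0)
  # sequence shorter than the motif yields no hits
  expect_equal(nrow(scan_sequence(m, "ACGT")), 0)
})

test_that("scanner agrees with the brute-force window oracle", {
  set.seed(61)
  bg <- c(A = 0.3, C = 0.2, G = 0.2, T = 0.3)
  for (i in 1:25) {
    pwm <- make_decoy_pwms(1, L = sample(4:8, 1))[[1]]
    seq <- paste(sample(c("A", "C", "G", "T", "N"), 50, TRUE,
                        prob = c(0.24, 0.24, 0.24, 0.24, 0.04)),
                 collapse = "")
    for (tf in c(0.5, 0.8)) {
      got <- scan_sequence(pwm, seq, tf, background = bg)
      want <- oracle_scan(pwm, seq, tf, bg)
      expect_equal(got$offset, want$offset)
      expect_equal(got$strand, want$strand)
      expect_equal(got$score, want$score, tolerance = 1e-9)
    }
  }
})

test_that("reverse-complement symmetry: hits map across strands", {
  set.seed(62)
  pwm <- make_decoy_pwms(1, L = 6)[[1]]
  bg <- rep(0.25, 4)
  for (i in 1:10) {
    seq <- paste(sample(c("A", "C", "G", "T"), 60, TRUE), collapse = "")
    fwd <- scan_sequence(pwm, seq, 0.6, background = bg)
    rev <- scan_sequence(pwm, revcomp(seq), 0.6, background = bg)
    # a + hit at offset o appears as a - hit at n - L - o and vice versa
    n <- nchar(seq); L <- ncol(pwm$matrix)
    expect_setequal(paste(fwd$offset, fwd$strand),
                    paste(n - L - rev$offset,
                          ifelse(rev$strand == "+", "-", "+")))
  }
})

test_that("hypergeometric p matches exact enumeration to 1e-10", {
  # spec example: 5 of 5 targets hit, 0 of 5 background
  t5 <- setNames(rep("ACGTACGTACGT", 5), paste0("t", 1:5))
  p_direct <- phyper(5 - 1, 5, 5, 5, lower.tail = FALSE)
  expect_equal(p_direct, 1 / choose(10, 5), tolerance = 1e-12)
  set.seed(63)
  for (i in 1:50) {
    N <- sample(5:30, 1)
    K <- sample.int(N, 1)
    n <- sample.int(N, 1)
    k <- sample.int(min(K, n), 1)
    expect_equal(phyper(k - 1, K, N - K, n, lower.tail = FALSE),
                 oracle_hyper_upper(k, K, N, n), tolerance = 1e-10)
  }
})

test_that("enrich_motifs scores targets against background", {
  set.seed(64)
  m <- default_motifs()
  klf <- m[["KLF_like_synthetic"]]
  cons <- pwm_consensus(klf)
  mk_seq <- function(with_motif) {
    s <- paste(sample(c("A", "C", "G", "T"), 80, TRUE), collapse = "")
    if (with_motif) paste0(substr(s, 1, 30), cons, substr(s, 41, 80)) else s
  }
  targets <- setNames(vapply(1:8, function(i) mk_seq(TRUE), ""),
                      paste0("t", 1:8))
  background <- setNames(vapply(1:10, function(i) mk_seq(FALSE), ""),
                         paste0("b", 1:10))
  res <- enrich_motifs(targets, background, m)
  expect_equal(res$motif[1], "KLF_like_synthetic")
  expect_equal(res$k[1], 8)
  expect_true(res$p[1] < 0.01)
  expect_true(all(res$fdr >= res$p - 1e-12))
  expect_error(enrich_motifs(character(), background, m), "non-empty")
  # equal hit rates: fold near 1, p large
  res0 <- enrich_motifs(targets, targets, list(klf))
  expect_equal(res0$fold, 1)
  expect_gte(res0$p, 0.5)
})

test_that("bh_adjust matches the step-up rule and p.adjust", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_adjust(0.2), 0.2)
  expect_equal(bh_adjust(rep(1, 4)), rep(1, 4))
  # hand-computed: sorted (0.01,0.04,0.5): 3*0.01/1=0.03, 3*0.04/2=0.06, 0.5
  expect_equal(bh_adjust(c(0.5, 0.01, 0.04)), c(0.5, 0.03, 0.06))
  set.seed(65)
  for (i in 1:10) {
    p <- runif(sample(1:40, 1))
    adj <- bh_adjust(p)
    expect_equal(adj, p.adjust(p, "BH"))
    # monotone in sorted p
    expect_true(all(diff(adj[order(p)]) >= -1e-12))
  }
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("gc_matched_subsample matches the target GC histogram", {
  set.seed(66)
  mk <- function(gc, n, len = 100) vapply(seq_len(n), function(i)
    paste(sample(c("A", "C", "G", "T"), len, TRUE,
                 prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
          collapse = ""), "")
  targets <- mk(0.5, 30)
  background <- c(mk(0.2, 60), mk(0.5, 60), mk(0.8, 60))
  sub <- gc_matched_subsample(background, targets, bins = 5, seed = 1)
  # subsample reproduces the targets' GC histogram (up to rounding)
  bin_of <- function(s) pmin(pmax(findInterval(
    flowreg:::gc_fraction(s), seq(0, 1, by = 0.2),
    rightmost.closed = TRUE), 1L), 5L)
  prop_sub <- tabulate(bin_of(sub), 5) / length(sub)
  prop_tgt <- tabulate(bin_of(targets), 5) / length(targets)
  expect_equal(prop_sub, prop_tgt, tolerance = 0.02)
  # determinism under a seed
  sub2 <- gc_matched_subsample(background, targets, bins = 5, seed = 1)
  expect_identical(sub, sub2)
})

test_that("planted motif ranks first among decoys", {
  set.seed(67)
  decoys <- make_decoy_pwms(10)
  firsts <- 0L
  for (s in 1:3) {
    cfg <- sim_config(n_genes = 40, n_common = 50, n_gained = 40,
                      n_lost = 30, peak_length_range = c(150, 250),
                      assays = "H3K27ac", seed = 400 + s)
    b <- generate_dataset(cfg)
    klf <- b$peaks$peak_id[b$peaks$class == "gained"]
    common <- b$peaks$peak_id[b$peaks$class == "common"]
    res <- enrich_motifs(b$sequences[klf], b$sequences[common],
                         c(default_motifs()["KLF_like_synthetic"], decoys))
    firsts <- firsts + (res$motif[1] == "KLF_like_synthetic")
  }
  expect_gte(firsts, 2)
})
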