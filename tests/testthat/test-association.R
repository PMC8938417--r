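# Regulatory domains, peak-gene association, DE cross-tab, correlation,
# gene-set overlap.

test_that("single-gene domain follows the basal-plus-extension rule", {
  g <- data.frame(gene_id = "g1", chrom = "chr1", tss = 1500000,
                  strand = "+", tx_end = NA_real_,
                  exon_starts = NA_character_, exon_ends = NA_character_)
  d <- build_regulatory_domains(g, chrom_lengths = c(chr1 = 1e7))
  expect_equal(d$start, 500000)
  expect_equal(d$end, 2500000)
  expect_equal(d$basal_start, 1495000)
  expect_equal(d$basal_end, 1501000)
})

test_that("neighbouring basal regions bound the extension", {
  g <- data.frame(gene_id = c("g1", "g2"), chrom = "chr1",
                  tss = c(1000000, 1100000), strand = "+",
                  tx_end = NA_real_, exon_starts = NA_character_,
                  exon_ends = NA_character_)
  d <- build_regulatory_domains(g, chrom_lengths = c(chr1 = 1e7))
  expect_equal(d$end[1], 1095000)   # g2 basal start
  expect_equal(d$start[2], 1001000) # g1 basal end
})

test_that("domains clip at chromosome bounds and error on bad TSS", {
  g <- data.frame(gene_id = "g1", chrom = "chr1", tss = 2000,
                  strand = "+", tx_end = NA_real_,
                  exon_starts = NA_character_, exon_ends = NA_character_)
  d <- build_regulatory_domains(g, chrom_lengths = c(chr1 = 1e7))
  expect_equal(d$start, 0)
  g$tss <- 2e7
  expect_error(build_regulatory_domains(g, chrom_lengths = c(chr1 = 1e7)),
               "outside chromosome")
})

test_that("domains match the brute-force oracle on random layouts", {
  set.seed(77)
  cl <- c(chr1 = 5e6, chr2 = 3e6)
  for (rep in 1:25) {
    g <- random_gene_layout(sample(3:25, 1), cl)
    d <- build_regulatory_domains(g, chrom_lengths = cl)
    o <- oracle_domains(g, 5000, 1000, 1e6, cl)
    expect_equal(d$start, o$start)
    expect_equal(d$end, o$end)
    # invariants: basal contained, 1 Mb and chromosome bounds respected
    expect_true(all(d$start <= d$basal_start & d$basal_end <= d$end))
    expect_true(all(d$start >= pmax(0, g$tss - 1e6 - 5000)))
    expect_true(all(d$start >= 0 & d$end <= cl[g$chrom]))
    expect_true(all(d$start >= g$tss - 1e6 | d$start == d$basal_start))
    expect_true(all(d$end <= g$tss + 1e6 | d$end == d$basal_end))
  }
})

test_that("peaks associate with every domain containing their midpoint", {
  g <- data.frame(gene_id = c("g1", "g2"), chrom = "chr1",
                  tss = c(1000000, 1100000), strand = "+",
                  tx_end = NA_real_, exon_starts = NA_character_,
                  exon_ends = NA_character_)
  dom <- build_regulatory_domains(g, chrom_lengths = c(chr1 = 1e7))
  pk <- genomic_intervals("chr1", c(1050000, 9000000), c(1050400, 9000400),
                          name = c("p1", "p2"))
  pk$dynamics <- c("gained", "gained")
  assoc <- associate_peaks_to_genes(pk, dom)
  # p1 midpoint sits between the two TSSs, inside both domains
  expect_setequal(assoc$pairs$gene_id[assoc$pairs$peak_id == "p1"],
                  c("g1", "g2"))
  expect_false("p2" %in% assoc$pairs$peak_id)
  expect_equal(assoc$gene_counts$gained, c(1L, 1L))
})

test_that("association_summary computes the cross-tab percentages", {
  gc <- data.frame(gene_id = c("u1", "u2", "d1"),
                   gained = c(1L, 0L, 0L), lost = c(0L, 0L, 2L),
                   common = c(0L, 0L, 0L))
  assoc <- list(gene_counts = gc)
  de <- data.frame(gene_id = c("u1", "u2", "d1"),
                   direction = c("up", "up", "down"))
  s <- association_summary(assoc, de)
  cell <- function(dir, cl) s$pct_genes_with_peak[s$direction == dir &
                                                    s$class == cl]
  expect_equal(cell("up", "gained"), 50)
  expect_equal(cell("down", "lost"), 100)
  expect_equal(cell("up", "lost"), 0)
  expect_equal(s$mean_peaks_per_gene[s$direction == "down" &
                                       s$class == "lost"], 2)
  # empty direction group -> NA cells
  s2 <- association_summary(assoc, de[de$direction == "up", ])
  expect_true(all(is.na(s2$pct_genes_with_peak[s2$direction == "down"])))
})

test_that("directional recovery holds on synthetic bundles", {
  ok <- logical(3)
  for (i in 1:3) {
    cfg <- sim_config(n_genes = 150, n_common = 60, n_gained = 60,
                      n_lost = 50, assoc_prob = 0.7, assays = "H3K27ac",
                      with_sequences = FALSE, seed = 100 + i)
    b <- generate_dataset(cfg)
    pk <- genomic_intervals(b$peaks$chrom, b$peaks$start, b$peaks$end,
                            name = b$peaks$peak_id)
    pk$dynamics <- b$peaks$class
    assoc <- associate_peaks_to_genes(pk, b$domains)
    s <- association_summary(assoc, b$de)
    cell <- function(dir, cl) s$pct_genes_with_peak[s$direction == dir &
                                                      s$class == cl]
    ok[i] <- cell("up", "gained") > cell("down", "gained") &&
      cell("down", "lost") > cell("up", "lost")
  }
  expect_true(all(ok))
})

test_that("correlation matches the textbook formula to 1e-12", {
  set.seed(55)
  gc <- data.frame(gene_id = sprintf("g%02d", 1:20),
                   gained = rpois(20, 2), lost = 0L, common = 0L)
  de <- data.frame(gene_id = gc$gene_id, log2fc = rnorm(20),
                   fdr = runif(20), direction = "ns")
  got <- peakcount_expression_correlation(list(gene_counts = gc), de,
                                          "gained")
  x <- gc$gained; y <- de$log2fc
  r_oracle <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  t_oracle <- r_oracle * sqrt((20 - 2) / (1 - r_oracle^2))
  p_oracle <- 2 * pt(-abs(t_oracle), 20 - 2)
  expect_equal(got$r, r_oracle, tolerance = 1e-12)
  expect_equal(got$p, p_oracle, tolerance = 1e-12)

  # perfect linearity and zero-variance flagging
  gc$gained <- seq_len(20)
  de$log2fc <- seq_len(20) * 0.5
  expect_equal(peakcount_expression_correlation(
    list(gene_counts = gc), de, "gained")$r, 1, tolerance = 1e-12)
  de$log2fc <- rep(1, 20)
  got <- peakcount_expression_correlation(list(gene_counts = gc), de,
                                          "gained")
  expect_true(got$flagged)
  expect_true(is.na(got$r))
  expect_error(peakcount_expression_correlation(
    list(gene_counts = gc[1:2, ]), de[1:2, ], "gained"), "at least 3")
})

test_that("gene_set_overlap reports both denominators and maps orthologs", {
  ov <- gene_set_overlap(c("g1", "g2", "g3"), c("g2", "g3", "g4"))
  expect_equal(ov$n_intersect, 2)
  expect_equal(ov$pct_jaccard, 50)
  expect_equal(ov$pct_of_a, 200 / 3)
  expect_equal(gene_set_overlap("a", "b")$pct_jaccard, 0)
  map <- data.frame(from = c("h1", "h1"), to = c("g1", "g9"))
  ov <- gene_set_overlap(c("g1", "g2"), c("h1", "h2"), map)
  expect_equal(ov$n_intersect, 1)
  expect_equal(ov$n_unmapped, 1)
  expect_error(gene_set_overlap(character(), "b"), "non-empty")
})
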