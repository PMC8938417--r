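# Seeded generator: determinism, truth completeness, planted fractions,
# motif planting.

small_cfg <- function(seed = 1, ...) {
  sim_config(n_genes = 60, n_common = 30, n_gained = 25, n_lost = 20,
             peak_length_range = c(150, 250), seed = seed, ...)
}

test_that("sim_config validates its invariants", {
  expect_error(sim_config(frac_up = 1.2), "\\[0, 1\\]")
  expect_error(sim_config(frac_up = 0.7, frac_down = 0.5), "<= 1")
  expect_error(sim_config(n_genes = 0), "positive")
  expect_error(sim_config(peak_length_range = c(20, 100)), ">= 50")
})

test_that("same config and seed give byte-identical bundles", {
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  generate_dataset(small_cfg(seed = 5), outdir = d1)
  generate_dataset(small_cfg(seed = 5), outdir = d2)
  f1 <- sort(list.files(d1))
  expect_identical(f1, sort(list.files(d2)))
  for (f in f1)
    expect_identical(readLines(file.path(d1, f), warn = FALSE),
                     readLines(file.path(d2, f), warn = FALSE),
                     label = f)
  # a different seed changes the bundle
  d3 <- withr::local_tempdir()
  generate_dataset(small_cfg(seed = 6), outdir = d3)
  expect_false(identical(readLines(file.path(d1, "genes.tsv")),
                         readLines(file.path(d3, "genes.tsv"))))
})

test_that("emitted files parse cleanly and agree with the truth manifest", {
  d <- withr::local_tempdir()
  b <- generate_dataset(small_cfg(seed = 8), outdir = d)
  expect_no_warning({
    genes <- read_gene_model(file.path(d, "genes.tsv"))
    de <- read_de_table(file.path(d, "de_table.tsv"))
    seqs <- read_fasta(file.path(d, "peaks.fasta"))
    beds <- lapply(list.files(d, pattern = "\\.bed$", full.names = TRUE),
                   read_bed, strict = TRUE)
  })
  expect_equal(nrow(genes), 60)
  expect_equal(nrow(de), 60)
  truth <- jsonlite::read_json(file.path(d, "truth.json"),
                               simplifyVector = TRUE)
  # every emitted peak appears exactly once in the truth table
  expect_equal(nrow(truth$peaks), nrow(b$peaks))
  expect_false(anyDuplicated(truth$peaks$peak_id) > 0)
  expect_setequal(names(seqs), b$peaks$peak_id)
  per_assay <- table(b$peaks$assay, b$peaks$class)
  expect_true(all(per_assay[, "common"] == 30 & per_assay[, "gained"] == 25 &
                    per_assay[, "lost"] == 20))
  # replicate BEDs carry exactly the member peaks of their condition
  rep1 <- read_bed(file.path(d, "H3K27ac_flow_rep1.bed"))
  flow_ids <- b$peaks$peak_id[b$peaks$assay == "H3K27ac" &
                                b$peaks$class %in% c("common", "gained")]
  expect_setequal(rep1$name, flow_ids)
  # replicate jitter is at most 10 bp
  tr <- b$peaks[match(rep1$name, b$peaks$peak_id), ]
  expect_true(all(abs(rep1$start - tr$start) <= 10))
  # DE directions encode the FDR gate
  expect_true(all(de$fdr[de$direction != "ns"] < 0.05))
  expect_true(all(de$fdr[de$direction == "ns"] >= 0.05))
})

test_that("targeted placement fraction stays within binomial bounds of pi", {
  # pooled across seeds: empirical association fraction within 3 SE
  pi0 <- 0.7
  targeted <- 0L
  total <- 0L
  for (s in 1:6) {
    b <- generate_dataset(sim_config(n_genes = 100, n_common = 10,
                                     n_gained = 50, n_lost = 40,
                                     assoc_prob = pi0, assays = "H3K27ac",
                                     with_sequences = FALSE, seed = 200 + s))
    g <- b$peaks[b$peaks$class == "gained", ]
    targeted <- targeted + sum(!is.na(g$target_gene))
    total <- total + nrow(g)
    # targeted gained peaks really sit inside their up-gene's domain
    tg <- g[!is.na(g$target_gene), ]
    dom <- b$domains[match(tg$target_gene, b$domains$gene_id), ]
    mid <- floor((tg$start + tg$end) / 2)
    expect_true(all(mid >= dom$start & mid < dom$end &
                      tg$chrom == dom$chrom))
    expect_true(all(b$de$direction[match(tg$target_gene,
                                         b$de$gene_id)] == "up"))
  }
  se <- sqrt(pi0 * (1 - pi0) / total)
  expect_lt(abs(targeted / total - pi0), 3 * se)
})

test_that("null configuration plants no association signal", {
  b <- generate_dataset(sim_config(n_genes = 80, n_common = 20,
                                   n_gained = 30, n_lost = 30,
                                   assoc_prob = 0, q_target = 0.05,
                                   q_background = 0.05,
                                   assays = "H3K27ac", seed = 33))
  expect_true(all(is.na(b$peaks$target_gene)))
  # plant rates do not differ by class beyond noise: pooled rate ~ 2*0.05
  plants_per_class <- table(factor(
    b$peaks$class[match(b$motif_plants$peak_id, b$peaks$peak_id)],
    levels = c("common", "gained", "lost")))
  rate <- as.numeric(plants_per_class) /
    (2 * as.numeric(table(factor(b$peaks$class,
                                 levels = c("common", "gained", "lost")))))
  expect_true(all(rate < 0.25))
})

test_that("plant_motif embeds a PWM instance at the recorded position", {
  set.seed(91)
  m <- default_motifs()[["ETS_like_synthetic"]]
  seq <- strrep("A", 60)
  for (i in 1:20) {
    pl <- plant_motif(seq, m)
    expect_equal(nchar(pl$sequence), 60)
    embedded <- substr(pl$sequence, pl$offset + 1, pl$offset + 10)
    if (pl$strand == "+") {
      expect_equal(embedded, pl$instance)
    } else {
      # reverse complement of the instance appears on the + strand
      expect_equal(embedded, revcomp(pl$instance))
    }
  }
  # empty motif: unchanged
  expect_equal(plant_motif(seq, "")$sequence, seq)
  expect_error(plant_motif("ACGT", m), "too short")
})

test_that("simulate_count_expression plants the stated linear relation", {
  sim <- simulate_count_expression(5000, slope = 0.6, noise_sd = 0.8,
                                   lambda = 2, seed = 12)
  expect_equal(length(sim$counts), 5000)
  r_hat <- cor(sim$counts, sim$log2fc)
  expect_lt(abs(r_hat - sim$expected_r), 0.05)
})
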