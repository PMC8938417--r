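# Seeded, fully in-silico datasets with planted structure: a genome, a
# gene model, two-condition replicate peak sets per assay, a DE table
# whose up/down genes are preferentially proximal to gained/lost peaks,
# and peak sequences carrying planted motifs, plus a ground-truth
# manifest for recovery tests.

#' Simulation configuration
#'
#' Defaults describe a small two-condition experiment with the structure
#' the pipeline is designed to detect: a fifth of genes upregulated,
#' gained peaks placed inside upregulated genes' regulatory domains with
#' probability \code{assoc_prob} (mirrored for lost/down), and KLF-like /
#' ETS-like motifs planted in gained / lost peak sequences.
#'
#' @param n_chroms number of chromosomes.
#' @param chrom_length chromosome length in bp.
#' @param n_genes total genes, spread evenly over chromosomes.
#' @param n_common,n_gained,n_lost peak counts per class, per assay.
#' @param peak_length_range min/max peak length in bp (min 50).
#' @param frac_up,frac_down fractions of genes up-/down-regulated.
#' @param lfc_mean,lfc_sd log2 fold-change distribution of DE genes;
#'   non-DE genes get log2fc ~ Normal(0, 0.1).
#' @param assoc_prob probability that a gained (lost) peak is placed
#'   inside a randomly chosen upregulated (downregulated) gene's
#'   regulatory domain rather than uniformly.
#' @param q_target,q_background per-sequence motif planting probability in
#'   the designated class and elsewhere.
#' @param gc_content background GC fraction of peak sequences.
#' @param cross_link_prob probability that an ATAC peak is placed within
#'   0-100 bp of a same-class H3K27ac peak, planting cross-assay overlap
#'   structure.
#' @param assays assays to simulate.
#' @param with_sequences generate peak sequences (disable to speed up
#'   runs that only exercise interval logic).
#' @param basal_up,basal_down,max_ext regulatory-domain parameters used
#'   for placement.
#' @param de_fdr FDR threshold encoded into the DE table.
#' @param seed RNG seed; the full bundle is deterministic given the seed.
#' @return a validated \code{sim_config} list.
#' @export
sim_config <- function(n_chroms = 3, chrom_length = 1e7, n_genes = 500,
                       n_common = 400, n_gained = 200, n_lost = 150,
                       peak_length_range = c(200, 500),
                       frac_up = 0.2, frac_down = 0.15,
                       lfc_mean = 2, lfc_sd = 0.5,
                       assoc_prob = 0.7,
                       q_target = 0.6, q_background = 0.05,
                       gc_content = 0.41, cross_link_prob = 0.25,
                       assays = c("H3K27ac", "ATAC"),
                       with_sequences = TRUE,
                       basal_up = 5000, basal_down = 1000, max_ext = 1e6,
                       de_fdr = 0.05, seed = 1L) {
  cfg <- as.list(environment())
  probs <- c(frac_up, frac_down, assoc_prob, q_target, q_background,
             gc_content, cross_link_prob)
  if (any(probs < 0 | probs > 1)) stop("probabilities must lie in [0, 1]")
  if (frac_up + frac_down > 1) stop("frac_up + frac_down must be <= 1")
  counts <- c(n_chroms, n_genes, n_common, n_gained, n_lost)
  if (any(counts <= 0)) stop("counts must be positive")
  if (peak_length_range[1] < 50) stop("peak lengths must be >= 50 bp")
  if (peak_length_range[2] < peak_length_range[1])
    stop("invalid peak_length_range")
  structure(cfg, class = "sim_config")
}

#' Built-in motif fixtures
#'
#' A KLF-like G-rich PWM and an ETS-like GGAA-core PWM, read from the
#' package's plain-text JASPAR-style fixture file. These are synthetic
#' stand-ins for the factor families reported at flow-responsive
#' enhancers, not database motifs.
#'
#' @return named list of two \code{pwm} objects.
#' @export
default_motifs <- function() {
  path <- system.file("extdata", "motifs", "core_motifs_synthetic.jaspar",
                      package = "flowreg")
  m <- read_motifs(path)
  stats::setNames(m, vapply(m, `[[`, "", "name"))
}

# A sharp PWM (97% consensus base) from a consensus string; used for
# decoys in tests and for planting. Sharpness is chosen so that an
# instance sampled from the PWM scores above the default 0.8 * s_max hit
# threshold with high probability (~74% for a 10-mer).
consensus_pwm <- function(name, consensus, major = 0.97) {
  idx <- match(strsplit(toupper(consensus), "")[[1]], BASES)
  stopifnot(!anyNA(idx))
  mat <- matrix((1 - major) / 3, nrow = 4, ncol = length(idx))
  mat[cbind(idx, seq_along(idx))] <- major
  new_pwm(name, mat)
}

#' Plant one motif instance in a sequence
#'
#' Samples an instance from the PWM's per-position base probabilities,
#' picks a uniform position and strand, and substitutes it into the
#' sequence (reverse-complemented for the minus strand). An empty motif
#' returns the sequence unchanged.
#'
#' @param sequence nucleotide string, longer than the motif.
#' @param pwm a \code{pwm} object (or a consensus string, converted to a
#'   sharp PWM).
#' @return list with \code{sequence}, \code{offset} (0-based, plus-strand
#'   coordinates), \code{strand} and \code{instance} (plus-strand
#'   orientation as sampled).
#' @export
plant_motif <- function(sequence, pwm) {
  if (is.character(pwm)) {
    if (!nzchar(pwm))
      return(list(sequence = sequence, offset = NA_integer_,
                  strand = NA_character_, instance = NA_character_))
    pwm <- consensus_pwm(pwm, pwm)
  }
  L <- ncol(pwm$matrix)
  n <- nchar(sequence)
  if (n <= L) stop("sequence too short to plant a ", L, " bp motif")
  inst <- paste(vapply(seq_len(L), function(j)
    sample(BASES, 1, prob = pwm$matrix[, j]), character(1)), collapse = "")
  offset <- sample.int(n - L + 1L, 1L) - 1L
  strand <- sample(c("+", "-"), 1)
  embedded <- if (strand == "-") revcomp(inst) else inst
  out <- paste0(substr(sequence, 1, offset),
                embedded,
                substr(sequence, offset + L + 1, n))
  list(sequence = out, offset = offset, strand = strand, instance = inst)
}

random_sequence <- function(len, gc) {
  paste(sample(BASES, len, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

# Collision-checked placement: returns a start or NA. `occupied` is a
# data.frame(chrom, start, end); margin keeps planted peaks far enough
# apart that replicate jitter can never merge them.
place_interval <- function(len, chrom, lo, hi, occupied, margin = 30,
                           tries = 200) {
  lo <- max(0, lo)
  if (hi - lo < 1) return(NA_real_)
  for (t in seq_len(tries)) {
    start <- floor(stats::runif(1, lo, hi))
    occ <- occupied[occupied$chrom == chrom, , drop = FALSE]
    if (nrow(occ) == 0 ||
        all(start >= occ$end + margin | start + len + margin <= occ$start))
      return(start)
  }
  NA_real_
}

#' Generate a synthetic dataset bundle
#'
#' Emits a gene model with uniform TSSs, a DE table, two replicate peak
#' BED sets per condition per assay (replicates jittered by at most 10
#' bp), per-peak sequences with planted motifs, and a ground-truth
#' manifest. Deterministic given \code{config$seed}.
#'
#' Structure planted: common peaks are present in both conditions; gained
#' peaks only under "flow", lost only under "static". Each gained peak is
#' placed inside a random upregulated gene's regulatory domain with
#' probability \code{assoc_prob} (else uniformly), mirrored for
#' lost/downregulated. KLF-like motifs are planted in gained-peak
#' sequences at rate \code{q_target} and ETS-like motifs in lost-peak
#' sequences, with rate \code{q_background} elsewhere.
#'
#' @param config a [sim_config()].
#' @param outdir optional directory; when given, all bundle files
#'   (genes.tsv, de_table.tsv, replicate BEDs, peaks.fasta, truth.json)
#'   are written there.
#' @return a list bundle: \code{genes}, \code{de}, \code{peaks} (truth
#'   peak table with \code{class}), \code{replicates} (named list of
#'   interval tables), \code{sequences}, \code{motif_plants},
#'   \code{domains}, \code{chrom_lengths}, \code{config}, \code{files}.
#' @export
generate_dataset <- function(config, outdir = NULL) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  chroms <- paste0("chr", seq_len(config$n_chroms))
  chrom_lengths <- stats::setNames(rep(config$chrom_length,
                                       config$n_chroms), chroms)

  ## gene model: TSS uniform per chromosome, away from the edges
  n_genes <- config$n_genes
  gchrom <- sort(rep_len(chroms, n_genes))
  tss <- floor(stats::runif(n_genes, config$basal_up,
                            config$chrom_length - config$basal_up))
  strand <- sample(c("+", "-"), n_genes, replace = TRUE)
  glen <- floor(stats::runif(n_genes, 2000, 20000))
  tx_end <- ifelse(strand == "+",
                   pmin(tss + glen, config$chrom_length),
                   pmax(tss - glen, 0))
  exons <- lapply(seq_len(n_genes), function(i) {
    k <- sample(2:5, 1)
    lo <- min(tss[i], tx_end[i]); hi <- max(tss[i], tx_end[i])
    cuts <- sort(floor(stats::runif(2 * k, lo, hi)))
    starts <- cuts[seq(1, 2 * k, by = 2)]
    ends <- cuts[seq(2, 2 * k, by = 2)]
    keep <- ends > starts
    list(starts = starts[keep], ends = ends[keep])
  })
  genes <- data.frame(
    gene_id = sprintf("g%04d", seq_len(n_genes)),
    chrom = gchrom, tss = tss, strand = strand, tx_end = tx_end,
    exon_starts = vapply(exons, function(e)
      paste(e$starts, collapse = ","), character(1)),
    exon_ends = vapply(exons, function(e)
      paste(e$ends, collapse = ","), character(1)),
    stringsAsFactors = FALSE
  )
  genes <- genes[order(genes$chrom, genes$tss), , drop = FALSE]
  rownames(genes) <- NULL

  ## DE table
  n_up <- round(config$frac_up * n_genes)
  n_down <- round(config$frac_down * n_genes)
  dir_true <- sample(c(rep("up", n_up), rep("down", n_down),
                       rep("ns", n_genes - n_up - n_down)))
  log2fc <- ifelse(dir_true == "up",
                   stats::rnorm(n_genes, config$lfc_mean, config$lfc_sd),
                   ifelse(dir_true == "down",
                          stats::rnorm(n_genes, -config$lfc_mean,
                                       config$lfc_sd),
                          stats::rnorm(n_genes, 0, 0.1)))
  # keep the sign consistent with the planted direction
  log2fc[dir_true == "up"] <- abs(log2fc[dir_true == "up"])
  log2fc[dir_true == "down"] <- -abs(log2fc[dir_true == "down"])
  fdr <- ifelse(dir_true == "ns",
                stats::runif(n_genes, config$de_fdr, 1),
                stats::runif(n_genes, 0, config$de_fdr * 0.98))
  de <- data.frame(gene_id = genes$gene_id, log2fc = log2fc, fdr = fdr,
                   direction = dir_true, stringsAsFactors = FALSE)

  domains <- build_regulatory_domains(genes, config$basal_up,
                                      config$basal_down, config$max_ext,
                                      chrom_lengths)
  up_dom <- domains[domains$gene_id %in% de$gene_id[de$direction == "up"], ]
  down_dom <- domains[domains$gene_id %in%
                        de$gene_id[de$direction == "down"], ]

  ## peak placement
  place_class <- function(n, class, target_dom, occupied) {
    rows <- vector("list", n)
    for (i in seq_len(n)) {
      len <- floor(stats::runif(1, config$peak_length_range[1],
                                config$peak_length_range[2] + 1))
      targeted <- nrow(target_dom) > 0 &&
        stats::runif(1) < config$assoc_prob
      start <- NA_real_
      chrom <- NA_character_
      tgene <- NA_character_
      if (targeted) {
        for (t in seq_len(50)) {
          j <- sample.int(nrow(target_dom), 1)
          # midpoint must fall inside the domain
          lo <- target_dom$start[j] - floor(len / 2)
          hi <- target_dom$end[j] - floor(len / 2)
          lo <- max(0, lo)
          hi <- min(chrom_lengths[[target_dom$chrom[j]]] - len, hi)
          start <- place_interval(len, target_dom$chrom[j], lo, hi,
                                  occupied)
          if (!is.na(start)) {
            chrom <- target_dom$chrom[j]
            tgene <- target_dom$gene_id[j]
            break
          }
        }
        if (is.na(start)) stop("could not place targeted ", class,
                               " peak after bounded retries")
      } else {
        for (t in seq_len(50)) {
          chrom <- sample(chroms, 1)
          start <- place_interval(len, chrom, 0,
                                  chrom_lengths[[chrom]] - len, occupied)
          if (!is.na(start)) break
        }
        if (is.na(start)) stop("could not place ", class, " peak")
      }
      rows[[i]] <- data.frame(chrom = chrom, start = start,
                              end = start + len, class = class,
                              target_gene = tgene,
                              stringsAsFactors = FALSE)
      occupied <- rbind(occupied,
                        rows[[i]][, c("chrom", "start", "end")])
    }
    list(rows = do.call(rbind, rows), occupied = occupied)
  }

  empty_occ <- data.frame(chrom = character(), start = numeric(),
                          end = numeric())
  all_peaks <- list()
  h3_peaks <- NULL
  for (assay in config$assays) {
    occupied <- empty_occ
    assay_rows <- list()
    for (class in c("common", "gained", "lost")) {
      n <- config[[paste0("n_", class)]]
      target_dom <- switch(class, gained = up_dom, lost = down_dom,
                           common = up_dom[0, ])
      linked <- 0L
      rows <- vector("list", n)
      for (i in seq_len(n)) {
        placed <- FALSE
        if (assay != "H3K27ac" && !is.null(h3_peaks) &&
            stats::runif(1) < config$cross_link_prob) {
          cand <- h3_peaks[h3_peaks$class == class, , drop = FALSE]
          if (nrow(cand) > 0) {
            j <- sample.int(nrow(cand), 1)
            len <- floor(stats::runif(1, config$peak_length_range[1],
                                      config$peak_length_range[2] + 1))
            gap <- floor(stats::runif(1, 0, 101))
            side <- sample(c(-1, 1), 1)
            start <- if (side > 0) cand$end[j] + gap else
              cand$start[j] - gap - len
            start <- max(0, min(start,
                                chrom_lengths[[cand$chrom[j]]] - len))
            occ <- occupied[occupied$chrom == cand$chrom[j], ,
                            drop = FALSE]
            if (nrow(occ) == 0 ||
                all(start >= occ$end + 30 |
                    start + len + 30 <= occ$start)) {
              rows[[i]] <- data.frame(chrom = cand$chrom[j],
                                      start = start, end = start + len,
                                      class = class,
                                      target_gene = NA_character_,
                                      stringsAsFactors = FALSE)
              occupied <- rbind(occupied,
                                rows[[i]][, c("chrom", "start", "end")])
              placed <- TRUE
              linked <- linked + 1L
            }
          }
        }
        if (!placed) {
          pc <- place_class(1, class, target_dom, occupied)
          rows[[i]] <- pc$rows
          occupied <- pc$occupied
        }
      }
      cls <- do.call(rbind, rows)
      assay_rows[[class]] <- cls
    }
    peaks <- do.call(rbind, assay_rows)
    peaks$assay <- assay
    peaks$peak_id <- sprintf("%s_%s_%04d", assay, peaks$class,
                             stats::ave(seq_len(nrow(peaks)), peaks$class,
                                        FUN = seq_along))
    rownames(peaks) <- NULL
    if (assay == "H3K27ac") h3_peaks <- peaks
    all_peaks[[assay]] <- peaks
  }
  peaks <- do.call(rbind, all_peaks)
  rownames(peaks) <- NULL

  ## replicate BED sets with <= 10 bp jitter
  replicates <- list()
  for (assay in config$assays) {
    ap <- peaks[peaks$assay == assay, , drop = FALSE]
    for (condition in c("static", "flow")) {
      member <- ap$class == "common" |
        (condition == "flow" & ap$class == "gained") |
        (condition == "static" & ap$class == "lost")
      sub <- ap[member, , drop = FALSE]
      for (rep_i in 1:2) {
        shift <- sample(-10:10, nrow(sub), replace = TRUE)
        out <- genomic_intervals(sub$chrom, pmax(0, sub$start + shift),
                                 pmax(0, sub$start + shift) +
                                   (sub$end - sub$start),
                                 name = sub$peak_id)
        o <- order(out$chrom, out$start, method = "radix")
        replicates[[sprintf("%s_%s_rep%d", assay, condition, rep_i)]] <-
          out[o, , drop = FALSE]
      }
    }
  }

  ## sequences with planted motifs
  sequences <- NULL
  motif_plants <- data.frame(peak_id = character(), motif = character(),
                             offset = integer(), strand = character())
  if (config$with_sequences) {
    motifs <- default_motifs()
    klf <- motifs[[grep("KLF", names(motifs))[1]]]
    ets <- motifs[[grep("ETS", names(motifs))[1]]]
    seqs <- character(nrow(peaks))
    plants <- list()
    for (i in seq_len(nrow(peaks))) {
      s <- random_sequence(peaks$end[i] - peaks$start[i],
                           config$gc_content)
      rate <- function(m) switch(peaks$class[i],
        gained = if (identical(m, klf)) config$q_target else
          config$q_background,
        lost = if (identical(m, ets)) config$q_target else
          config$q_background,
        config$q_background)
      for (m in list(klf, ets)) {
        if (stats::runif(1) < rate(m)) {
          pl <- plant_motif(s, m)
          s <- pl$sequence
          plants[[length(plants) + 1L]] <- data.frame(
            peak_id = peaks$peak_id[i], motif = m$name,
            offset = pl$offset, strand = pl$strand)
        }
      }
      seqs[i] <- s
    }
    sequences <- stats::setNames(seqs, peaks$peak_id)
    if (length(plants)) motif_plants <- do.call(rbind, plants)
  }

  bundle <- list(genes = genes, de = de, peaks = peaks,
                 replicates = replicates, sequences = sequences,
                 motif_plants = motif_plants, domains = domains,
                 chrom_lengths = chrom_lengths, config = config,
                 files = character())

  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    files <- c(genes = file.path(outdir, "genes.tsv"),
               de_table = file.path(outdir, "de_table.tsv"),
               truth = file.path(outdir, "truth.json"))
    write_gene_model(genes, files[["genes"]])
    write_de_table(de, files[["de_table"]])
    for (nm in names(replicates)) {
      f <- file.path(outdir, paste0(nm, ".bed"))
      write_bed(replicates[[nm]], f)
      files[[nm]] <- f
    }
    if (!is.null(sequences)) {
      files[["peaks_fasta"]] <- file.path(outdir, "peaks.fasta")
      write_fasta(sequences, files[["peaks_fasta"]])
    }
    truth <- list(
      config = unclass(config),
      peaks = peaks,
      de = de[, c("gene_id", "direction")],
      motif_plants = motif_plants,
      chrom_lengths = as.list(chrom_lengths)
    )
    jsonlite::write_json(truth, files[["truth"]], auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
    bundle$files <- files
  }
  bundle
}

#' Simulate a planted linear count-expression relationship
#'
#' Per-gene peak counts are Poisson(\code{lambda}) and log2 fold changes
#' follow \code{slope * count + Normal(0, noise_sd)}. The closed-form
#' expected Pearson correlation is
#' \code{slope * sd(x) / sqrt(slope^2 var(x) + noise_sd^2)} with
#' \code{var(x) = lambda}; used to verify correlation recovery.
#'
#' @param n number of genes.
#' @param slope linear effect of peak count on log2 fold change.
#' @param noise_sd residual standard deviation.
#' @param lambda Poisson mean of the peak counts.
#' @param seed RNG seed.
#' @return list with \code{counts}, \code{log2fc} and \code{expected_r}.
#' @export
simulate_count_expression <- function(n, slope = 0.5, noise_sd = 1,
                                      lambda = 2, seed = NULL) {
  with_seed(seed, {
    x <- stats::rpois(n, lambda)
    y <- slope * x + stats::rnorm(n, 0, noise_sd)
    list(counts = x, log2fc = y,
         expected_r = slope * sqrt(lambda) /
           sqrt(slope^2 * lambda + noise_sd^2))
  })
}
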