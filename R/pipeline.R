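# File-based pipeline stages behind a single orchestrator. Every stage
# reads its inputs from disk and writes TSV/BED/JSON outputs plus a log
# line, so stages can run standalone from the CLI or chained by
# run_pipeline(). Output naming is timestamp-free for diffability.

#' Pipeline run configuration
#'
#' Collects all thresholds used across stages (documented defaults mirror
#' the conventional analysis constants: 100 bp cross-assay pairing, FDR
#' 0.05 gates, 1 Mb regulatory domains), the stage list, file locations
#' and the seed. The configuration is echoed verbatim into the run
#' manifest.
#'
#' @param outdir output directory.
#' @param seed top-level RNG seed; all stage randomness derives from it.
#' @param stages stages to run, in dependency order.
#' @param assays assays processed by classification and downstream
#'   stages.
#' @param data_dir directory holding the input bundle (replicate BEDs,
#'   genes.tsv, de_table.tsv, peaks.fasta); defaults to
#'   \code{<outdir>/data}, where the simulate stage writes.
#' @param max_gap cross-assay pairing distance in bp.
#' @param de_fdr,peak_fdr FDR thresholds for expression and occupancy.
#' @param basal_up,basal_down,max_ext regulatory-domain parameters in bp.
#' @param threshold_frac motif-scan hit threshold.
#' @param promoter_window,tts_window annotation windows in bp.
#' @param motif_file motif library; defaults to the packaged synthetic
#'   KLF/ETS fixtures.
#' @param motif_assay assay whose gained peaks are the motif targets.
#' @param sim simulation configuration for the simulate stage.
#' @param log_level \code{"info"} or \code{"quiet"}.
#' @return a \code{run_config} list.
#' @export
run_config <- function(outdir, seed = 1L,
                       stages = c("simulate", "classify", "crossassay",
                                  "annotate", "associate", "motifs",
                                  "report"),
                       assays = c("H3K27ac", "ATAC"),
                       data_dir = file.path(outdir, "data"),
                       max_gap = 100, de_fdr = 0.05, peak_fdr = 0.05,
                       basal_up = 5000, basal_down = 1000, max_ext = 1e6,
                       threshold_frac = 0.8,
                       promoter_window = c(1000, 100), tts_window = 1000,
                       motif_file = NULL, motif_assay = "ATAC",
                       sim = sim_config(seed = seed),
                       log_level = "info") {
  stopifnot(max_gap >= 0, de_fdr > 0, peak_fdr > 0, basal_up > 0,
            basal_down > 0, max_ext > 0, threshold_frac > 0,
            threshold_frac <= 1)
  cfg <- as.list(environment())
  structure(cfg, class = "run_config")
}

log_line <- function(config, stage, msg) {
  line <- sprintf("[%s] %s", stage, msg)
  if (identical(config$log_level, "info")) message(line)
  cat(line, "\n", sep = "", file = file.path(config$outdir, "run.log"),
      append = TRUE)
}

stage_path <- function(config, ...) file.path(config$outdir, ...)

require_file <- function(path, produced_by) {
  if (!file.exists(path))
    stop("missing input '", path, "'; run the '", produced_by,
         "' stage (or point data_dir at an existing bundle) first")
  path
}

stage_simulate <- function(config) {
  bundle <- generate_dataset(config$sim, outdir = config$data_dir)
  log_line(config, "simulate",
           sprintf("%d genes, %d truth peaks, %d replicate files",
                   nrow(bundle$genes), nrow(bundle$peaks),
                   length(bundle$replicates)))
  invisible(bundle)
}

read_classified <- function(config, assay) {
  x <- read_bed(require_file(stage_path(config,
                                        paste0("classified_", assay,
                                               ".bed")), "classify"))
  x$dynamics <- sub(sprintf("^%s_(gained|lost|common)_\\d+$", assay),
                    "\\1", x$name)
  if (!all(x$dynamics %in% DYNAMICS_LEVELS))
    stop("classified BED names do not carry a dynamics class")
  x$assay <- assay
  x
}

stage_classify <- function(config) {
  for (assay in config$assays) {
    reps <- lapply(c("static_rep1", "static_rep2", "flow_rep1",
                     "flow_rep2"), function(tag)
      read_bed(require_file(file.path(config$data_dir,
                                      sprintf("%s_%s.bed", assay, tag)),
                            "simulate")))
    static <- consensus_replicates(reps[[1]], reps[[2]], "static", assay)
    flow <- consensus_replicates(reps[[3]], reps[[4]], "flow", assay)
    cls <- classify_peak_dynamics(static, flow)
    write_bed(cls[, c("chrom", "start", "end", "name", "score", "strand")],
              stage_path(config, paste0("classified_", assay, ".bed")))
    for (cl in c("gained", "lost", "common"))
      write_bed(cls[cls$dynamics == cl,
                    c("chrom", "start", "end", "name", "score", "strand"),
                    drop = FALSE],
                stage_path(config, sprintf("%s_%s.bed", assay, cl)))
    tab <- table(factor(cls$dynamics, levels = c("gained", "lost",
                                                 "common")))
    log_line(config, "classify",
             sprintf("%s: %d gained, %d lost, %d common (union %d)",
                     assay, tab[["gained"]], tab[["lost"]],
                     tab[["common"]], nrow(cls)))
  }
  invisible(NULL)
}

matrix_to_df <- function(counts) {
  data.frame(query_class = rownames(counts),
             as.data.frame.matrix(counts), row.names = NULL)
}

stage_crossassay <- function(config) {
  if (length(config$assays) < 2) {
    log_line(config, "crossassay", "skipped: fewer than two assays")
    return(invisible(NULL))
  }
  a1 <- read_classified(config, config$assays[1])
  a2 <- read_classified(config, config$assays[2])
  m12 <- cross_assay_matrix(a2, a1, max_gap = config$max_gap,
                            direction = paste0(config$assays[2], "_vs_",
                                               config$assays[1]))
  m21 <- cross_assay_matrix(a1, a2, max_gap = config$max_gap,
                            direction = paste0(config$assays[1], "_vs_",
                                               config$assays[2]))
  for (m in list(m12, m21)) {
    write_tsv(matrix_to_df(m$counts),
              stage_path(config, paste0("crossassay_", m$direction,
                                        ".tsv")))
    log_line(config, "crossassay",
             sprintf("%s: %d query peaks", m$direction, sum(m$counts)))
  }
  invisible(NULL)
}

stage_annotate <- function(config) {
  genes <- read_gene_model(require_file(file.path(config$data_dir,
                                                  "genes.tsv"),
                                        "simulate"))
  for (assay in config$assays) {
    cls <- read_classified(config, assay)
    ann <- annotate_peaks(cls, genes,
                          promoter_window = config$promoter_window,
                          tts_window = config$tts_window)
    write_tsv(ann, stage_path(config, paste0("annotation_", assay,
                                             ".tsv")))
    write_tsv(annotation_summary(ann, cls$dynamics),
              stage_path(config, paste0("annotation_summary_", assay,
                                        ".tsv")))
    log_line(config, "annotate",
             sprintf("%s: %d peaks annotated", assay, nrow(ann)))
  }
  invisible(NULL)
}

infer_chrom_lengths <- function(genes, peaks, pad) {
  chroms <- unique(c(genes$chrom, peaks$chrom))
  vapply(chroms, function(ch) {
    max(c(genes$tss[genes$chrom == ch] + 1,
          peaks$end[peaks$chrom == ch]), 0) + pad
  }, numeric(1))
}

stage_associate <- function(config) {
  genes <- read_gene_model(require_file(file.path(config$data_dir,
                                                  "genes.tsv"),
                                        "simulate"))
  de <- read_de_table(require_file(file.path(config$data_dir,
                                             "de_table.tsv"), "simulate"),
                      fdr_threshold = config$de_fdr)
  truth_file <- file.path(config$data_dir, "truth.json")
  chrom_lengths <- if (file.exists(truth_file)) {
    unlist(jsonlite::read_json(truth_file)$chrom_lengths)
  } else NULL
  for (assay in config$assays) {
    cls <- read_classified(config, assay)
    cl_len <- if (is.null(chrom_lengths))
      infer_chrom_lengths(genes, cls, config$max_ext) else chrom_lengths
    domains <- build_regulatory_domains(genes, config$basal_up,
                                        config$basal_down,
                                        config$max_ext, cl_len)
    if (assay == config$assays[1])
      write_bed(genomic_intervals(domains$chrom, domains$start,
                                  domains$end, name = domains$gene_id,
                                  score = 0, strand = domains$strand),
                stage_path(config, "domains.bed"))
    assoc <- associate_peaks_to_genes(cls, domains)
    write_tsv(assoc$gene_counts,
              stage_path(config, paste0("gene_peak_counts_", assay,
                                        ".tsv")))
    write_tsv(association_summary(assoc, de),
              stage_path(config, paste0("association_", assay, ".tsv")))
    cors <- do.call(rbind, lapply(c("gained", "lost", "common"),
                                  function(cl) {
      ct <- peakcount_expression_correlation(assoc, de, cl)
      data.frame(class = cl, r = ct$r, p = ct$p, n = ct$n)
    }))
    write_tsv(cors, stage_path(config, paste0("correlation_", assay,
                                              ".tsv")))
    log_line(config, "associate",
             sprintf("%s: %d peak-gene pairs over %d domains", assay,
                     nrow(assoc$pairs), nrow(domains)))
  }
  invisible(NULL)
}

# Recover the original (FASTA) ids of classified peaks by overlap with a
# named replicate peak set.
map_classified_to_ids <- function(classified, rep_peaks) {
  hit <- nearest_in_set(classified, rep_peaks, max_gap = 0)
  ids <- rep(NA_character_, nrow(classified))
  ids[hit$query] <- rep_peaks$name[hit$subject]
  ids
}

stage_motifs <- function(config) {
  assay <- config$motif_assay
  fasta <- require_file(file.path(config$data_dir, "peaks.fasta"),
                        "simulate")
  seqs <- read_fasta(fasta)
  cls <- read_classified(config, assay)
  flow_rep <- read_bed(require_file(file.path(config$data_dir,
                                              sprintf("%s_flow_rep1.bed",
                                                      assay)),
                                    "simulate"))
  ids <- map_classified_to_ids(cls, flow_rep)
  target_ids <- ids[cls$dynamics == "gained"]
  bg_ids <- ids[cls$dynamics == "common"]
  targets <- seqs[stats::na.omit(target_ids)]
  background <- seqs[stats::na.omit(bg_ids)]
  motif_file <- if (is.null(config$motif_file))
    system.file("extdata", "motifs", "core_motifs_synthetic.jaspar",
                package = "flowreg") else config$motif_file
  motifs <- read_motifs(motif_file)
  res <- enrich_motifs(targets, background, motifs,
                       threshold_frac = config$threshold_frac)
  write_tsv(res, stage_path(config, paste0("motif_enrichment_", assay,
                                           ".tsv")))
  log_line(config, "motifs",
           sprintf("%s: %d motifs scored on %d targets vs %d background",
                   assay, nrow(res), length(targets), length(background)))
  invisible(res)
}

stage_report <- function(config) {
  report <- list(seed = config$seed, assays = config$assays)
  for (assay in config$assays) {
    f <- stage_path(config, paste0("classified_", assay, ".bed"))
    if (file.exists(f)) {
      cls <- read_classified(config, assay)
      report$class_counts[[assay]] <-
        as.list(table(factor(cls$dynamics,
                             levels = c("gained", "lost", "common"))))
    }
    for (tag in c("annotation_summary_", "association_", "correlation_",
                  "motif_enrichment_")) {
      f <- stage_path(config, paste0(tag, assay, ".tsv"))
      if (file.exists(f))
        report[[sub("_$", "", tag)]][[assay]] <- read_tsv(f)
    }
  }
  cross <- list.files(config$outdir, pattern = "^crossassay_.*\\.tsv$")
  for (f in cross)
    report$crossassay[[sub("^crossassay_(.*)\\.tsv$", "\\1", f)]] <-
      read_tsv(stage_path(config, f))
  jsonlite::write_json(report, stage_path(config, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       na = "null")
  files <- sort(setdiff(list.files(config$outdir, recursive = TRUE),
                        c("manifest.json")))
  manifest <- list(
    config = unclass(config),
    files = lapply(files, function(f) {
      p <- stage_path(config, f)
      list(path = f, size = file.info(p)$size,
           md5 = unname(tools::md5sum(p)))
    })
  )
  manifest$config$sim <- unclass(manifest$config$sim)
  jsonlite::write_json(manifest, stage_path(config, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       na = "null")
  log_line(config, "report",
           sprintf("report.json + manifest.json over %d files",
                   length(files)))
  invisible(report)
}

#' Run the analysis pipeline
#'
#' Executes the enabled stages in dependency order: simulate, classify,
#' crossassay, annotate, associate, motifs, report. Every stage writes
#' its outputs plus a log line under \code{config$outdir}; the report
#' stage aggregates class counts, annotation fractions, the association
#' cross-tab, correlation statistics, the cross-assay matrices and the
#' motif table into \code{report.json}, and writes a \code{manifest.json}
#' with the configuration, seed and checksums of every output file.
#' Identical configuration and seed give byte-identical output bundles.
#'
#' @param config a [run_config()].
#' @return the report list, invisibly (NULL when the report stage is
#'   disabled).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
  logf <- file.path(config$outdir, "run.log")
  if (file.exists(logf)) unlink(logf)
  order <- c("simulate", "classify", "crossassay", "annotate",
             "associate", "motifs", "report")
  unknown <- setdiff(config$stages, order)
  if (length(unknown)) stop("unknown stage(s): ",
                            paste(unknown, collapse = ", "))
  out <- NULL
  for (st in order[order %in% config$stages]) {
    out <- switch(st,
      simulate = stage_simulate(config),
      classify = stage_classify(config),
      crossassay = stage_crossassay(config),
      annotate = stage_annotate(config),
      associate = stage_associate(config),
      motifs = stage_motifs(config),
      report = stage_report(config))
  }
  invisible(out)
}
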