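# Readers and writers for the plain-text formats the pipeline exchanges:
# BED3/5/6, the tab-delimited gene model, DE tables, FASTA and TSV/JSON
# results. All coordinates are converted to 0-based half-open on the way
# in and written back unchanged.

fmt_num <- function(x) {
  vapply(x, function(v) {
    if (is.na(v)) return(".")
    format(v, scientific = FALSE, trim = TRUE, drop0trailing = TRUE)
  }, character(1))
}

#' Read a BED file
#'
#' Accepts BED3 to BED6. Track, browser and comment lines are skipped.
#' BED's half-open 0-based convention is preserved as-is.
#'
#' @param path file path.
#' @param strict if \code{TRUE}, a malformed line (fewer than 3 fields,
#'   non-numeric or negative coordinates, or \code{start >= end}) is an
#'   error; otherwise the line is rejected with a warning and reading
#'   continues.
#' @return an interval table (see [genomic_intervals()]) in file order.
#' @export
read_bed <- function(path, strict = FALSE) {
  if (!file.exists(path)) stop("BED file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  lines <- lines[!grepl("^(#|track\\b|browser\\b)", lines)]
  if (length(lines) == 0) return(empty_intervals())
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  starts <- suppressWarnings(as.numeric(vapply(fields, function(f)
    if (length(f) >= 2) f[2] else NA_character_, character(1))))
  ends <- suppressWarnings(as.numeric(vapply(fields, function(f)
    if (length(f) >= 3) f[3] else NA_character_, character(1))))
  bad <- nf < 3 | is.na(starts) | is.na(ends) | starts < 0 | starts >= ends
  if (any(bad)) {
    msg <- sprintf("rejecting %d malformed BED line(s) in %s (first: '%s')",
                   sum(bad), path, lines[which(bad)[1]])
    if (strict) stop(msg)
    warning(msg)
    fields <- fields[!bad]; nf <- nf[!bad]
    starts <- starts[!bad]; ends <- ends[!bad]
  }
  if (length(fields) == 0) return(empty_intervals())
  getf <- function(i) vapply(fields, function(f)
    if (length(f) >= i) f[i] else NA_character_, character(1))
  x <- data.frame(
    chrom = getf(1), start = starts, end = ends,
    name = if (max(nf) >= 4) getf(4) else NA_character_,
    score = if (max(nf) >= 5) suppressWarnings(as.numeric(getf(5)))
            else NA_real_,
    strand = if (max(nf) >= 6) getf(6) else NA_character_,
    stringsAsFactors = FALSE
  )
  validate_intervals(x)
  x
}

#' Write intervals as BED
#'
#' Emits BED3, BED4, BED5 or BED6 depending on which optional columns are
#' populated; for well-formed input, \code{write_bed(read_bed(f))}
#' round-trips coordinates and names byte-identically.
#'
#' @param x interval table.
#' @param path output path.
#' @export
write_bed <- function(x, path) {
  validate_intervals(x)
  has_strand <- "strand" %in% names(x) && any(!is.na(x$strand))
  has_score <- has_strand || ("score" %in% names(x) && any(!is.na(x$score)))
  has_name <- has_score || ("name" %in% names(x) && any(!is.na(x$name)))
  cols <- list(x$chrom, fmt_num(x$start), fmt_num(x$end))
  if (has_name) cols <- c(cols, list(ifelse(is.na(x$name), ".", x$name)))
  if (has_score) cols <- c(cols, list(fmt_num(x$score)))
  if (has_strand) cols <- c(cols, list(ifelse(is.na(x$strand), ".", x$strand)))
  writeLines(do.call(paste, c(cols, sep = "\t")), path)
  invisible(path)
}

#' Read a tab-delimited gene model
#'
#' Expected header columns: \code{gene_id}, \code{chrom}, \code{tss},
#' \code{strand}; optional \code{tx_end}, \code{exon_starts},
#' \code{exon_ends} (comma-delimited, BED-style 0-based half-open
#' coordinates). \code{tss} is the 0-based coordinate of the transcription
#' start base; for minus-strand genes \code{tx_end < tss}.
#'
#' @param path file path.
#' @return a \code{data.frame} of gene records.
#' @export
read_gene_model <- function(path) {
  if (!file.exists(path)) stop("gene model file not found: ", path)
  g <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("gene_id", "chrom", "tss", "strand")
  if (!all(need %in% names(g)))
    stop("gene model must have columns: ", paste(need, collapse = ", "))
  if (!all(g$strand %in% c("+", "-")))
    stop("gene strand must be '+' or '-'")
  if (anyDuplicated(g$gene_id)) stop("duplicate gene_id in gene model")
  if (!"tx_end" %in% names(g)) g$tx_end <- NA_real_
  if (!"exon_starts" %in% names(g)) g$exon_starts <- NA_character_
  if (!"exon_ends" %in% names(g)) g$exon_ends <- NA_character_
  g$tss <- as.numeric(g$tss)
  g$tx_end <- as.numeric(g$tx_end)
  g$exon_starts <- as.character(g$exon_starts)
  g$exon_ends <- as.character(g$exon_ends)
  g
}

#' @rdname read_gene_model
#' @param genes gene table as returned by [read_gene_model()].
#' @export
write_gene_model <- function(genes, path) {
  out <- genes[, intersect(c("gene_id", "chrom", "tss", "strand", "tx_end",
                             "exon_starts", "exon_ends"), names(genes))]
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# Parse one gene's comma-delimited exon columns into an interval table.
gene_exons <- function(gene) {
  if (is.na(gene$exon_starts) || !nzchar(gene$exon_starts))
    return(empty_intervals())
  s <- as.numeric(strsplit(gene$exon_starts, ",", fixed = TRUE)[[1]])
  e <- as.numeric(strsplit(gene$exon_ends, ",", fixed = TRUE)[[1]])
  if (length(s) != length(e)) stop("exon_starts/exon_ends length mismatch for ",
                                   gene$gene_id)
  genomic_intervals(gene$chrom, s, e)
}

#' Read a differential-expression table
#'
#' Expected header columns: \code{gene_id}, \code{log2fc}, \code{fdr}. A
#' \code{direction} label is assigned: \code{up}/\code{down} when
#' \code{fdr < fdr_threshold} with positive/negative \code{log2fc},
#' otherwise \code{ns}.
#'
#' @param path file path.
#' @param fdr_threshold FDR cutoff for calling a gene differentially
#'   expressed (default 0.05).
#' @return a \code{data.frame(gene_id, log2fc, fdr, direction)}.
#' @export
read_de_table <- function(path, fdr_threshold = 0.05) {
  if (!file.exists(path)) stop("DE table not found: ", path)
  de <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("gene_id", "log2fc", "fdr")
  if (!all(need %in% names(de)))
    stop("DE table must have columns: ", paste(need, collapse = ", "))
  de$log2fc <- as.numeric(de$log2fc)
  de$fdr <- as.numeric(de$fdr)
  if (any(de$fdr < 0 | de$fdr > 1, na.rm = TRUE))
    stop("FDR values must lie in [0, 1]")
  de$direction <- de_direction(de$log2fc, de$fdr, fdr_threshold)
  de
}

de_direction <- function(log2fc, fdr, fdr_threshold = 0.05) {
  ifelse(fdr < fdr_threshold & log2fc > 0, "up",
         ifelse(fdr < fdr_threshold & log2fc < 0, "down", "ns"))
}

#' @rdname read_de_table
#' @param de DE table.
#' @export
write_de_table <- function(de, path) {
  utils::write.table(de[, c("gene_id", "log2fc", "fdr")], path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read sequences from a FASTA file
#'
#' Wrapped or unwrapped lines; nucleotides are upper-cased, \code{N}
#' allowed.
#'
#' @param path file path.
#' @return a named character vector of sequences.
#' @export
read_fasta <- function(path) {
  ss <- Biostrings::readBStringSet(path)
  out <- toupper(as.character(ss))
  names(out) <- sub("\\s.*$", "", names(ss))
  out
}

#' @rdname read_fasta
#' @param seqs named character vector of sequences.
#' @param width line-wrap width.
#' @export
write_fasta <- function(seqs, path, width = 70) {
  ss <- Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(ss, path, width = width)
  invisible(path)
}

#' Reverse complement of nucleotide sequences
#'
#' @param x character vector of sequences (A/C/G/T/N).
#' @return reverse-complemented sequences.
#' @export
revcomp <- function(x) {
  out <- as.character(
    Biostrings::reverseComplement(Biostrings::DNAStringSet(x))
  )
  names(out) <- names(x)
  out
}

write_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_tsv <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}

# Evaluate code under a temporary RNG state seeded with `seed`; the
# caller's RNG stream is untouched. seed = NULL runs code as-is.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}
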