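# Basal-plus-extension regulatory domains, peak-to-gene association over
# those domains, and the association statistics against differential
# expression, including the cross-species gene-set overlap.

#' Build basal-plus-extension regulatory domains
#'
#' Every gene gets a basal region around its TSS (strand-oriented:
#' \code{basal_up} bp upstream, \code{basal_down} bp downstream) which is
#' then extended in both directions to the nearest neighbouring gene's
#' basal region edge, but no further than \code{max_ext} bp from the TSS
#' and never past the chromosome ends. A domain always contains its own
#' basal region even when neighbouring basal regions overlap it.
#'
#' @param genes gene model table.
#' @param basal_up,basal_down basal region extent upstream/downstream of
#'   the TSS in bp (defaults 5000 and 1000).
#' @param max_ext maximum extension from the TSS in bp (default 1 Mb).
#' @param chrom_lengths named vector of chromosome lengths.
#' @return \code{data.frame(gene_id, chrom, start, end, basal_start,
#'   basal_end, tss, strand)} with half-open coordinates.
#' @export
build_regulatory_domains <- function(genes, basal_up = 5000,
                                     basal_down = 1000, max_ext = 1e6,
                                     chrom_lengths) {
  stopifnot(all(genes$chrom %in% names(chrom_lengths)))
  len <- as.numeric(chrom_lengths[genes$chrom])
  if (any(genes$tss < 0 | genes$tss >= len))
    stop("gene TSS outside chromosome bounds")
  bs <- pmax(0, ifelse(genes$strand == "+", genes$tss - basal_up,
                       genes$tss - basal_down))
  be <- pmin(len, ifelse(genes$strand == "+", genes$tss + basal_down,
                         genes$tss + basal_up))
  ds <- numeric(nrow(genes))
  de <- numeric(nrow(genes))
  for (chr in unique(genes$chrom)) {
    g <- which(genes$chrom == chr)
    clen <- chrom_lengths[[chr]]
    sbe <- sort(be[g])
    sbs <- sort(bs[g])
    # nearest basal edge at or left of / at or right of each TSS; a
    # gene's own basal spans its TSS so it never constrains itself
    li <- findInterval(genes$tss[g], sbe)
    left_nb <- ifelse(li >= 1, sbe[pmax(li, 1)], -Inf)
    ri <- findInterval(genes$tss[g] - 0.5, sbs) + 1
    right_nb <- ifelse(ri <= length(sbs), sbs[pmin(ri, length(sbs))], Inf)
    ds[g] <- pmin(bs[g], pmax(0, genes$tss[g] - max_ext, left_nb))
    de[g] <- pmax(be[g], pmin(clen, genes$tss[g] + max_ext, right_nb))
  }
  data.frame(gene_id = genes$gene_id, chrom = genes$chrom,
             start = ds, end = de, basal_start = bs, basal_end = be,
             tss = genes$tss, strand = genes$strand,
             stringsAsFactors = FALSE)
}

#' Associate peaks with genes through regulatory domains
#'
#' A peak associates, by its midpoint, with every gene whose regulatory
#' domain contains that midpoint; long peaks therefore count once. Per-
#' gene peak counts are tallied separately for each dynamics class.
#'
#' @param peaks classified peak table carrying \code{name} and
#'   \code{dynamics} columns.
#' @param domains domain table from [build_regulatory_domains()].
#' @return a list with \code{pairs} (\code{data.frame(peak_id, gene_id,
#'   dynamics)}) and \code{gene_counts} (one row per domain gene with
#'   columns \code{gained}, \code{lost}, \code{common}).
#' @export
associate_peaks_to_genes <- function(peaks, domains) {
  validate_intervals(peaks)
  stopifnot("dynamics" %in% names(peaks))
  mids <- peak_midpoint(peaks)
  pair_list <- list()
  for (chr in unique(domains$chrom)) {
    dset <- which(domains$chrom == chr)
    pset <- which(peaks$chrom == chr)
    if (length(pset) == 0) next
    m <- mids[pset]
    for (j in dset) {
      inside <- pset[m >= domains$start[j] & m < domains$end[j]]
      if (length(inside))
        pair_list[[length(pair_list) + 1L]] <- data.frame(
          peak_id = peaks$name[inside],
          gene_id = domains$gene_id[j],
          dynamics = peaks$dynamics[inside])
    }
  }
  pairs <- if (length(pair_list)) do.call(rbind, pair_list) else
    data.frame(peak_id = character(), gene_id = character(),
               dynamics = character())
  counts <- data.frame(gene_id = domains$gene_id)
  for (cl in c("gained", "lost", "common")) {
    tab <- table(factor(pairs$gene_id[pairs$dynamics == cl],
                        levels = domains$gene_id))
    counts[[cl]] <- as.integer(tab)
  }
  list(pairs = pairs, gene_counts = counts)
}

#' Cross-tabulate peak association against expression direction
#'
#' For every combination of expression direction (up, down) and peak
#' dynamics class, reports the percentage of that direction's genes with
#' at least one associated peak of the class, plus the mean number of
#' associated peaks per gene. This is the statistic behind "x% of
#' upregulated genes associated with at least one gained peak".
#'
#' @param assoc association result from [associate_peaks_to_genes()].
#' @param de DE table with \code{gene_id} and \code{direction} columns.
#' @param directions direction groups to tabulate.
#' @return long-format \code{data.frame(direction, class,
#'   pct_genes_with_peak, mean_peaks_per_gene, n_genes)}; cells for an
#'   empty direction group are \code{NA}.
#' @export
association_summary <- function(assoc, de,
                                directions = c("up", "down")) {
  gc <- assoc$gene_counts
  rows <- list()
  for (dir in directions) {
    ids <- de$gene_id[de$direction == dir]
    idx <- match(ids, gc$gene_id)
    for (cl in c("gained", "lost", "common")) {
      cnt <- gc[[cl]][idx]
      cnt[is.na(cnt)] <- 0L
      rows[[length(rows) + 1L]] <- data.frame(
        direction = dir, class = cl,
        pct_genes_with_peak = if (length(ids) == 0) NA_real_ else
          100 * mean(cnt > 0),
        mean_peaks_per_gene = if (length(ids) == 0) NA_real_ else
          mean(cnt),
        n_genes = length(ids))
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Pearson correlation between per-gene peak count and expression change
#'
#' Computes Pearson's r between the number of associated peaks of one
#' dynamics class and the gene's log2 fold change, with the two-sided
#' p-value from the t distribution on n - 2 degrees of freedom.
#'
#' @param assoc association result from [associate_peaks_to_genes()].
#' @param de DE table with defined \code{log2fc}.
#' @param peak_class one of \code{"gained"}, \code{"lost"},
#'   \code{"common"}.
#' @param genes optional subset of gene ids; defaults to all DE-table
#'   genes present in the domain set.
#' @return list with \code{r}, \code{p}, \code{n} and \code{flagged}
#'   (TRUE when r is undefined because either variable has zero
#'   variance).
#' @export
peakcount_expression_correlation <- function(assoc, de, peak_class,
                                             genes = NULL) {
  stopifnot(peak_class %in% c("gained", "lost", "common"))
  gc <- assoc$gene_counts
  de <- de[!is.na(de$log2fc), , drop = FALSE]
  if (!is.null(genes)) de <- de[de$gene_id %in% genes, , drop = FALSE]
  idx <- match(de$gene_id, gc$gene_id)
  x <- gc[[peak_class]][idx]
  x[is.na(x)] <- 0L
  y <- de$log2fc
  n <- length(x)
  if (n < 3) stop("need at least 3 genes with defined log2fc")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    return(list(r = NA_real_, p = NA_real_, n = n, flagged = TRUE))
  ct <- stats::cor.test(x, y, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value, n = n, flagged = FALSE)
}

#' Overlap between two gene sets, optionally across species
#'
#' Reports the intersection size under both common denominators:
#' Jaccard (\code{|A n B| / |A u B|}) and fraction of the first set
#' (\code{|A n B| / |A|}). When an ortholog map is given, set \code{b} is
#' first translated into \code{a}'s namespace; a gene counts as shared if
#' any ortholog matches. The map may be many-to-many.
#'
#' @param a,b character vectors of gene ids; both must be non-empty.
#' @param ortholog_map optional \code{data.frame(from, to)} translating
#'   \code{b}-namespace ids (\code{from}) to \code{a}-namespace ids
#'   (\code{to}).
#' @return list with \code{n_a}, \code{n_b}, \code{n_intersect},
#'   \code{pct_jaccard}, \code{pct_of_a}, \code{n_unmapped}.
#' @export
gene_set_overlap <- function(a, b, ortholog_map = NULL) {
  if (length(a) == 0 || length(b) == 0)
    stop("gene sets must be non-empty")
  a <- unique(a)
  b <- unique(b)
  n_unmapped <- 0L
  b_ns <- b
  if (!is.null(ortholog_map)) {
    stopifnot(all(c("from", "to") %in% names(ortholog_map)))
    mapped <- ortholog_map$to[ortholog_map$from %in% b]
    n_unmapped <- sum(!b %in% ortholog_map$from)
    b_ns <- unique(mapped)
  }
  inter <- intersect(a, b_ns)
  uni <- union(a, b_ns)
  list(n_a = length(a), n_b = length(b), n_intersect = length(inter),
       pct_jaccard = 100 * length(inter) / length(uni),
       pct_of_a = 100 * length(inter) / length(a),
       n_unmapped = n_unmapped)
}
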