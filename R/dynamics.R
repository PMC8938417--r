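# Replicate consensus, gained/lost/common classification between two
# conditions, an optional count-based differential occupancy test, and the
# cross-assay overlap matrix.

DYNAMICS_LEVELS <- c("gained", "lost", "common", "unassigned")

#' Construct a consensus peak set
#'
#' @param condition condition label (e.g. \code{"static"}, \code{"flow"}).
#' @param assay assay label, one of \code{"H3K27ac"} or \code{"ATAC"}.
#' @param peaks interval table, sorted and deduplicated.
#' @return a \code{consensus_peak_set} object.
#' @export
consensus_peak_set <- function(condition, assay, peaks) {
  validate_intervals(peaks)
  o <- order(peaks$chrom, peaks$start, peaks$end, method = "radix")
  peaks <- peaks[o, , drop = FALSE]
  dup <- duplicated(peaks[, c("chrom", "start", "end")])
  peaks <- peaks[!dup, , drop = FALSE]
  rownames(peaks) <- NULL
  structure(list(condition = condition, assay = assay, peaks = peaks),
            class = "consensus_peak_set")
}

#' Replicate-consensus peaks for one condition
#'
#' A peak is retained iff it overlaps (distance 0, book-ended included) a
#' peak in the other replicate; retained overlapping peaks are merged to
#' their union interval. This is the set-level surrogate for joint
#' two-replicate peak calling.
#'
#' @param rep1,rep2 interval tables for the two replicates.
#' @param condition,assay labels stored on the result.
#' @return a \code{consensus_peak_set}.
#' @examples
#' r1 <- genomic_intervals("chr1", 100, 200)
#' r2 <- genomic_intervals("chr1", 150, 260)
#' consensus_replicates(r1, r2)$peaks  # chr1:[100,260)
#' @export
consensus_replicates <- function(rep1, rep2, condition = "condition",
                                 assay = "H3K27ac") {
  keep1 <- unique(nearest_in_set(rep1, rep2, max_gap = 0)$query)
  keep2 <- unique(nearest_in_set(rep2, rep1, max_gap = 0)$query)
  pool <- rbind(
    rep1[keep1, c("chrom", "start", "end"), drop = FALSE],
    rep2[keep2, c("chrom", "start", "end"), drop = FALSE]
  )
  merged <- merge_touching(pool)$merged
  consensus_peak_set(condition, assay, merged)
}

#' Classify peaks as gained, lost or common between two conditions
#'
#' Peaks overlapping across conditions (distance 0) are merged to their
#' union interval and labelled \code{common}; peaks present only in
#' \code{set2} are \code{gained}, only in \code{set1} are \code{lost}.
#' The counts of gained, lost and common peaks always sum to the size of
#' the merged union set, and swapping the two conditions exchanges gained
#' and lost exactly.
#'
#' @param set1 consensus peak set for the reference condition (e.g.
#'   static).
#' @param set2 consensus peak set for the second condition (e.g. flow);
#'   must be the same assay.
#' @return an interval table with columns \code{chrom, start, end, name,
#'   score, strand, assay, dynamics}.
#' @export
classify_peak_dynamics <- function(set1, set2) {
  stopifnot(inherits(set1, "consensus_peak_set"),
            inherits(set2, "consensus_peak_set"))
  if (!identical(set1$assay, set2$assay))
    stop("assay mismatch: ", set1$assay, " vs ", set2$assay)
  p1 <- set1$peaks; p2 <- set2$peaks
  pool <- rbind(p1[, c("chrom", "start", "end"), drop = FALSE],
                p2[, c("chrom", "start", "end"), drop = FALSE])
  origin <- c(rep(1L, nrow(p1)), rep(2L, nrow(p2)))
  mg <- merge_touching(pool)
  merged <- mg$merged
  has1 <- tabulate(mg$groups[origin == 1L], nbins = nrow(merged)) > 0
  has2 <- tabulate(mg$groups[origin == 2L], nbins = nrow(merged)) > 0
  merged$assay <- set1$assay
  merged$dynamics <- ifelse(has1 & has2, "common",
                            ifelse(has2, "gained", "lost"))
  merged$name <- sprintf("%s_%s_%05d", set1$assay, merged$dynamics,
                         stats::ave(seq_len(nrow(merged)), merged$dynamics,
                                    FUN = seq_along))
  merged
}

#' Exact binomial test of differential occupancy from pooled counts
#'
#' For each peak with \code{x1} reads in condition 1 and \code{x2} in
#' condition 2, performs a two-sided exact binomial test of \code{x2}
#' successes in \code{x1 + x2} trials against the library-size null
#' \code{p0 = libsize2 / (libsize1 + libsize2)}, then BH-adjusts across
#' peaks. Peaks with adjusted FDR below \code{fdr_threshold} are flagged
#' differential. A peak with zero total count gets p = 1.
#'
#' @param counts1,counts2 non-negative integer read counts per peak.
#' @param libsize1,libsize2 positive library sizes.
#' @param fdr_threshold FDR gate (default 0.05).
#' @return \code{data.frame(counts1, counts2, p, fdr, differential)}.
#' @export
differential_occupancy_test <- function(counts1, counts2, libsize1,
                                        libsize2, fdr_threshold = 0.05) {
  stopifnot(length(counts1) == length(counts2),
            libsize1 > 0, libsize2 > 0)
  if (any(counts1 < 0) || any(counts2 < 0) ||
      any(counts1 != round(counts1)) || any(counts2 != round(counts2)))
    stop("counts must be non-negative integers")
  p0 <- libsize2 / (libsize1 + libsize2)
  p <- vapply(seq_along(counts1), function(i) {
    n <- counts1[i] + counts2[i]
    if (n == 0) return(1)
    stats::binom.test(counts2[i], n, p = p0)$p.value
  }, numeric(1))
  fdr <- bh_adjust(p)
  data.frame(counts1 = counts1, counts2 = counts2, p = p, fdr = fdr,
             differential = fdr < fdr_threshold)
}

#' Cross-assay overlap matrix
#'
#' Each classified query peak contributes one count to the cell (query
#' dynamics class, dynamics class of the nearest subject peak within
#' \code{max_gap} bp), or to the \code{none} column when no subject
#' qualifies. Row sums equal the query-set class sizes; dividing rows by
#' their sums gives the overlap fractions reported in cross-assay
#' comparisons.
#'
#' @param query_peaks,subject_peaks classified peak tables (from
#'   [classify_peak_dynamics()]) carrying a \code{dynamics} column.
#' @param max_gap pairing distance in bp; the conventional rule is
#'   "within 100 bp" (default 100).
#' @param direction free-text record of which assay is the query.
#' @return a list with the integer \code{counts} matrix
#'   (classes x classes + none) and \code{direction}.
#' @export
cross_assay_matrix <- function(query_peaks, subject_peaks, max_gap = 100,
                               direction = "query_vs_subject") {
  stopifnot("dynamics" %in% names(query_peaks))
  classes <- c("gained", "lost", "common")
  cols <- c(classes, "none")
  counts <- matrix(0L, nrow = length(classes), ncol = length(cols),
                   dimnames = list(query = classes, subject = cols))
  if (nrow(query_peaks) > 0) {
    partner <- rep("none", nrow(query_peaks))
    if (!is.null(subject_peaks) && nrow(subject_peaks) > 0) {
      stopifnot("dynamics" %in% names(subject_peaks))
      hit <- nearest_in_set(query_peaks, subject_peaks, max_gap = max_gap)
      partner[hit$query] <- subject_peaks$dynamics[hit$subject]
    }
    tab <- table(factor(query_peaks$dynamics, levels = classes),
                 factor(partner, levels = cols))
    counts[] <- as.integer(tab)
  }
  list(counts = counts, direction = direction)
}
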