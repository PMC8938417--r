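# Peak-to-feature annotation: each peak is assigned, by its midpoint, to
# exactly one of promoter, TTS, exon, intron or intergenic, with a fixed
# priority order mirroring the behaviour of standard peak annotators at
# this resolution.

FEATURE_LEVELS <- c("promoter", "TTS", "exon", "intron", "intergenic")

peak_midpoint <- function(x) floor((x$start + x$end) / 2)

# Signed strand-aware distance from a position to a TSS: negative
# upstream of the gene, positive downstream.
signed_tss_distance <- function(mid, tss, strand) {
  ifelse(strand == "+", mid - tss, tss - mid)
}

#' Annotate peaks to genomic features
#'
#' The annotation is decided by the peak midpoint with priority
#' promoter > TTS > exon > intron > intergenic. The promoter window is
#' strand-oriented \code{[TSS - upstream, TSS + downstream)}; the
#' TTS-proximal window extends \code{tts_window} bp either side of the
#' transcript end; intron means inside the gene body but in no exon.
#' Genes without a recorded transcript end contribute promoter calls only.
#' Annotation is invariant to gene-list order: ties are resolved by
#' feature priority, then smallest absolute TSS distance, then
#' lexicographic gene id.
#'
#' @param peaks interval table; the \code{name} column is used as peak id.
#' @param genes gene model table (see [read_gene_model()]).
#' @param promoter_window \code{c(upstream, downstream)} in bp around the
#'   TSS (default \code{c(1000, 100)}).
#' @param tts_window bp either side of the transcript end (default 1000).
#' @return \code{data.frame(peak_id, feature, gene_id, distance_to_tss)};
#'   \code{gene_id} is \code{NA} iff the feature is intergenic, and
#'   \code{distance_to_tss} refers to the nearest gene's TSS (NA on a
#'   chromosome with no genes).
#' @export
annotate_peaks <- function(peaks, genes, promoter_window = c(1000, 100),
                           tts_window = 1000) {
  validate_intervals(peaks)
  up <- promoter_window[1]
  down <- promoter_window[2]
  mids <- peak_midpoint(peaks)
  ids <- if ("name" %in% names(peaks) && !all(is.na(peaks$name)))
    peaks$name else sprintf("peak_%05d", seq_len(nrow(peaks)))
  exon_cache <- lapply(seq_len(nrow(genes)), function(j)
    gene_exons(genes[j, , drop = FALSE]))
  out <- vector("list", nrow(peaks))
  for (i in seq_len(nrow(peaks))) {
    g <- which(genes$chrom == peaks$chrom[i])
    if (length(g) == 0) {
      out[[i]] <- data.frame(peak_id = ids[i], feature = "intergenic",
                             gene_id = NA_character_,
                             distance_to_tss = NA_real_)
      next
    }
    m <- mids[i]
    d <- signed_tss_distance(m, genes$tss[g], genes$strand[g])
    is_prom <- d >= -up & d < down
    tx <- genes$tx_end[g]
    has_body <- !is.na(tx)
    is_tts <- has_body & abs(m - tx) <= tts_window
    in_body <- has_body & m >= pmin(genes$tss[g], tx) &
      m < pmax(genes$tss[g], tx)
    in_exon <- vapply(seq_along(g), function(k) {
      ex <- exon_cache[[g[k]]]
      nrow(ex) > 0 && any(m >= ex$start & m < ex$end)
    }, logical(1))
    feat <- rep(NA_integer_, length(g))
    feat[in_body] <- 4L                       # intron
    feat[in_body & in_exon] <- 3L             # exon
    feat[is_tts] <- 2L
    feat[is_prom] <- 1L
    nearest <- order(abs(d), genes$gene_id[g])[1]
    if (all(is.na(feat))) {
      out[[i]] <- data.frame(peak_id = ids[i], feature = "intergenic",
                             gene_id = NA_character_,
                             distance_to_tss = d[nearest])
    } else {
      best <- order(feat, abs(d), genes$gene_id[g], na.last = TRUE)[1]
      out[[i]] <- data.frame(peak_id = ids[i],
                             feature = FEATURE_LEVELS[feat[best]],
                             gene_id = genes$gene_id[g][best],
                             distance_to_tss = d[nearest])
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Feature-class fractions per dynamics class
#'
#' @param results annotation table from [annotate_peaks()].
#' @param classes per-peak dynamics labels, parallel to \code{results}.
#' @return a \code{data.frame} with one row per dynamics class, the five
#'   feature fractions (each non-empty row sums to 1) and the class size
#'   \code{n}; empty classes yield an all-zero row with \code{n = 0}.
#' @export
annotation_summary <- function(results, classes) {
  stopifnot(nrow(results) == length(classes))
  lv <- unique(classes)
  lv <- lv[order(match(lv, DYNAMICS_LEVELS, nomatch = 99), lv)]
  rows <- lapply(lv, function(cl) {
    f <- factor(results$feature[classes == cl], levels = FEATURE_LEVELS)
    n <- length(f)
    frac <- if (n == 0) rep(0, length(FEATURE_LEVELS)) else
      as.numeric(table(f)) / n
    stats::setNames(data.frame(cl, t(frac), n),
                    c("class", FEATURE_LEVELS, "n"))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
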