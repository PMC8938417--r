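#' Construct a table of genomic intervals
#'
#' Intervals follow the BED convention used throughout the package:
#' coordinates are 0-based, half-open \code{[start, end)}. All peak and
#' region coordinates handled by flowreg live in this representation;
#' 1-based formats are converted at I/O boundaries only.
#'
#' @param chrom chromosome names (character, non-empty).
#' @param start 0-based inclusive start coordinates.
#' @param end 0-based exclusive end coordinates; must satisfy
#'   \code{0 <= start < end}.
#' @param name optional interval identifiers.
#' @param score optional numeric scores.
#' @param strand optional strand (\code{"+"}, \code{"-"} or \code{NA});
#'   peaks are unstranded features and strand is ignored by all distance
#'   computations.
#' @return a \code{data.frame} with columns \code{chrom}, \code{start},
#'   \code{end}, \code{name}, \code{score}, \code{strand}.
#' @examples
#' genomic_intervals("chr1", 100, 200, name = "pkA", score = 5)
#' @export
genomic_intervals <- function(chrom, start, end, name = NA_character_,
                              score = NA_real_, strand = NA_character_) {
  n <- max(length(chrom), length(start), length(end))
  x <- data.frame(
    chrom  = rep_len(as.character(chrom), n),
    start  = rep_len(as.numeric(start), n),
    end    = rep_len(as.numeric(end), n),
    name   = rep_len(as.character(name), n),
    score  = rep_len(as.numeric(score), n),
    strand = rep_len(as.character(strand), n),
    stringsAsFactors = FALSE
  )
  validate_intervals(x)
  x
}

validate_intervals <- function(x) {
  stopifnot(is.data.frame(x), all(c("chrom", "start", "end") %in% names(x)))
  if (nrow(x) == 0) return(invisible(x))
  if (any(is.na(x$chrom)) || any(!nzchar(x$chrom)))
    stop("interval chromosome names must be non-empty")
  if (any(is.na(x$start)) || any(is.na(x$end)))
    stop("interval coordinates must not be NA")
  if (any(x$start < 0))
    stop("interval start coordinates must be >= 0")
  if (any(x$start >= x$end))
    stop("intervals must satisfy start < end (0-based half-open)")
  invisible(x)
}

empty_intervals <- function() {
  genomic_intervals(character(), numeric(), numeric())
}

# 1-based closed GRanges view of a half-open interval table; internal.
as_granges <- function(x) {
  GenomicRanges::GRanges(
    seqnames = x$chrom,
    ranges = IRanges::IRanges(start = x$start + 1, end = x$end)
  )
}

#' Distance between two genomic intervals
#'
#' The gap in bases between the nearest ends of two half-open intervals.
#' Overlapping or book-ended intervals have distance 0; intervals on
#' different chromosomes have undefined distance (\code{NA}). The "within
#' 100 bp" overlap rule used for cross-assay pairing is expressed as
#' \code{interval_distance(a, b) <= 100}.
#'
#' Vectorized over rows; \code{a} and \code{b} are recycled to a common
#' length.
#'
#' @param a,b interval tables (see [genomic_intervals()]).
#' @return numeric vector of distances in bp, \code{NA} where the
#'   chromosomes differ.
#' @examples
#' a <- genomic_intervals("chr1", 100, 200)
#' interval_distance(a, genomic_intervals("chr1", 250, 350))  # 50
#' interval_distance(a, genomic_intervals("chr1", 150, 300))  # 0
#' @export
interval_distance <- function(a, b) {
  n <- max(nrow(a), nrow(b))
  ai <- rep_len(seq_len(nrow(a)), n)
  bi <- rep_len(seq_len(nrow(b)), n)
  d <- pmax(0, pmax(a$start[ai], b$start[bi]) - pmin(a$end[ai], b$end[bi]))
  d[a$chrom[ai] != b$chrom[bi]] <- NA_real_
  d
}

#' Nearest subject interval for every query interval
#'
#' For each query, reports the subject interval minimizing
#' [interval_distance()] with distance at most \code{max_gap}. Equidistant
#' candidates are resolved deterministically: smaller start coordinate
#' first, then lexicographic name, then subject order.
#'
#' @param query,subjects interval tables.
#' @param max_gap maximum distance in bp for a pairing to be reported.
#' @return a \code{data.frame(query, subject, distance)} of row indices
#'   into \code{query} and \code{subjects}; queries with no qualifying
#'   subject are absent.
#' @export
nearest_in_set <- function(query, subjects, max_gap = Inf) {
  out0 <- data.frame(query = integer(), subject = integer(),
                     distance = numeric())
  if (nrow(query) == 0 || nrow(subjects) == 0) return(out0)
  gq <- as_granges(query)
  gs <- as_granges(subjects)
  dtn <- suppressWarnings(
    GenomicRanges::distanceToNearest(gq, gs, select = "arbitrary"))
  if (length(dtn) == 0) return(out0)
  q0 <- S4Vectors::queryHits(dtn)
  dmin <- as.numeric(S4Vectors::mcols(dtn)$distance)
  keep <- dmin <= max_gap
  if (!any(keep)) return(out0)
  q0 <- q0[keep]; dmin <- dmin[keep]
  # recover every subject at exactly the minimum distance (the nearest
  # call above picks an arbitrary tie): expand each query by its own
  # minimum distance, then take overlapping or book-ended subjects
  ex <- gq[q0]
  IRanges::ranges(ex) <- IRanges::IRanges(
    start = pmax(1, GenomicRanges::start(ex) - dmin),
    end = GenomicRanges::end(ex) + dmin)
  ov <- suppressWarnings(
    GenomicRanges::findOverlaps(ex, gs, maxgap = 0L))
  qh <- q0[S4Vectors::queryHits(ov)]
  sh <- S4Vectors::subjectHits(ov)
  d <- dmin[S4Vectors::queryHits(ov)]
  nm <- if ("name" %in% names(subjects)) as.character(subjects$name[sh])
        else rep(NA_character_, length(sh))
  o <- order(qh, subjects$start[sh], nm, sh, na.last = TRUE,
             method = "radix")
  qh <- qh[o]; sh <- sh[o]; d <- d[o]
  first <- !duplicated(qh)
  data.frame(query = qh[first], subject = sh[first], distance = d[first])
}

#' Find the nearest subject to a single query interval
#'
#' @param query a one-row interval table.
#' @param subjects interval table to search.
#' @param max_distance maximum distance in bp.
#' @return \code{NULL} if no subject lies within \code{max_distance} on the
#'   query's chromosome, otherwise a list with elements \code{subject}
#'   (one-row interval table), \code{distance} and \code{index}.
#' @export
find_nearest <- function(query, subjects, max_distance = Inf) {
  stopifnot(nrow(query) == 1)
  res <- nearest_in_set(query, subjects, max_gap = max_distance)
  if (nrow(res) == 0) return(NULL)
  list(subject = subjects[res$subject, , drop = FALSE],
       distance = res$distance, index = res$subject)
}

#' Pair every interval in one set with its nearest partner in another
#'
#' For each interval in \code{a}, reports the nearest interval in \code{b}
#' within \code{max_gap} bp, or nothing. Symmetric use (swapping \code{a}
#' and \code{b}) gives the reverse mapping. Deterministic given inputs.
#'
#' @param a,b interval tables.
#' @param max_gap maximum gap in bp (0 = overlap or book-ended only).
#' @return \code{data.frame(query, subject, distance, query_name,
#'   subject_name)}.
#' @export
intersect_sets <- function(a, b, max_gap = 0) {
  res <- nearest_in_set(a, b, max_gap = max_gap)
  res$query_name <- if ("name" %in% names(a)) a$name[res$query]
                    else NA_character_
  res$subject_name <- if ("name" %in% names(b)) b$name[res$subject]
                      else NA_character_
  res
}

# Merge overlapping or book-ended intervals (distance 0) into components.
# Returns the merged table plus a group id per input row, in input order.
merge_touching <- function(x) {
  if (nrow(x) == 0)
    return(list(merged = empty_intervals(), groups = integer()))
  o <- order(x$chrom, x$start, x$end, method = "radix")
  xo <- x[o, , drop = FALSE]
  g <- integer(nrow(xo))
  gid <- 0L
  cur_chr <- ""
  cur_end <- -Inf
  for (i in seq_len(nrow(xo))) {
    if (xo$chrom[i] != cur_chr || xo$start[i] > cur_end) {
      gid <- gid + 1L
      cur_chr <- xo$chrom[i]
      cur_end <- xo$end[i]
    } else {
      cur_end <- max(cur_end, xo$end[i])
    }
    g[i] <- gid
  }
  merged <- data.frame(
    chrom = tapply(xo$chrom, g, `[`, 1),
    start = as.numeric(tapply(xo$start, g, min)),
    end   = as.numeric(tapply(xo$end, g, max)),
    name  = NA_character_, score = NA_real_, strand = NA_character_,
    stringsAsFactors = FALSE
  )
  rownames(merged) <- NULL
  groups <- integer(nrow(x))
  groups[o] <- g
  list(merged = merged, groups = groups)
}
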