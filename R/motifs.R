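# PWM scanning and target-vs-background motif enrichment. Sequences are
# scored by log2-odds against a background base composition on both
# strands; enrichment uses sequence-level (>= 1 hit) counting and a
# hypergeometric upper tail, BH-adjusted across motifs.

BASES <- c("A", "C", "G", "T")

#' Construct a position weight matrix
#'
#' @param name motif name.
#' @param matrix 4 x L numeric matrix of per-position base probabilities,
#'   rows A, C, G, T; every column must sum to 1 (within 1e-6) and L must
#'   be at least 4.
#' @param background base composition over A/C/G/T used for log-odds
#'   scoring; defaults to uniform.
#' @return a \code{pwm} object.
#' @export
new_pwm <- function(name, matrix, background = rep(0.25, 4)) {
  stopifnot(is.matrix(matrix), nrow(matrix) == 4)
  if (ncol(matrix) < 4) stop("PWM must have length >= 4, got ", ncol(matrix))
  rownames(matrix) <- BASES
  csum <- colSums(matrix)
  if (any(abs(csum - 1) > 1e-6))
    stop("PWM columns must sum to 1 after normalization")
  background <- background / sum(background)
  names(background) <- BASES
  structure(list(name = name, matrix = matrix, background = background),
            class = "pwm")
}

#' @export
print.pwm <- function(x, ...) {
  cat(sprintf("PWM '%s' (length %d), consensus %s\n", x$name,
              ncol(x$matrix), pwm_consensus(x)))
  invisible(x)
}

#' Consensus sequence of a PWM (most probable base per position)
#' @param pwm a \code{pwm} object.
#' @export
pwm_consensus <- function(pwm) {
  paste(BASES[apply(pwm$matrix, 2, which.max)], collapse = "")
}

# Maximum achievable log2-odds score given a background composition.
pwm_max_score <- function(pwm, background = pwm$background) {
  lo <- log2(pwm$matrix / background)
  sum(apply(lo, 2, max))
}

normalize_counts <- function(counts, pseudocount) {
  tot <- colSums(counts)
  if (any(tot <= 0)) stop("motif matrix column with non-positive total")
  # probability-style input (HOMER): regularize at a nominal depth of 100
  if (all(counts <= 1 + 1e-9) && all(abs(tot - 1) < 0.05))
    counts <- counts * 100
  sweep(counts + pseudocount, 2, colSums(counts) + 4 * pseudocount, "/")
}

#' Read motifs from a JASPAR-style PFM or HOMER-style motif file
#'
#' Both dialects are auto-detected per record. JASPAR records carry four
#' base rows (optionally prefixed \code{A [ ... ]}) of counts; counts are
#' converted to probabilities with a per-base pseudocount:
#' \code{(c + pc) / (N + 4 pc)}. HOMER records carry one probability row
#' per position (columns A C G T).
#'
#' @param path motif file.
#' @param pseudocount per-base pseudocount (default 0.25).
#' @return a list of \code{pwm} objects.
#' @export
read_motifs <- function(path, pseudocount = 0.25) {
  if (!file.exists(path)) stop("motif file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  hdr <- grep("^>", lines)
  if (length(hdr) == 0) stop("no motif records (no '>' headers) in ", path)
  ends <- c(hdr[-1] - 1L, length(lines))
  motifs <- vector("list", length(hdr))
  for (i in seq_along(hdr)) {
    header <- sub("^>\\s*", "", lines[hdr[i]])
    body <- lines[seq(hdr[i] + 1L, ends[i])]
    if (hdr[i] + 1L > ends[i] || length(body) == 0)
      stop("motif record with empty body in ", path)
    hf <- strsplit(header, "[\t ]+")[[1]]
    jaspar_rows <- grepl("^[ACGTacgt]\\b|^[ACGTacgt]\\s*\\[", body)
    if (any(jaspar_rows)) {
      if (sum(jaspar_rows) != 4)
        stop("JASPAR record must have 4 base rows: ", header)
      vals <- lapply(body[jaspar_rows], function(l) {
        base <- toupper(substr(trimws(l), 1, 1))
        nums <- as.numeric(strsplit(trimws(gsub("^[ACGTacgt]|\\[|\\]", " ",
                                                l)), "\\s+")[[1]])
        list(base = base, nums = nums[!is.na(nums)])
      })
      ord <- match(BASES, vapply(vals, `[[`, "", "base"))
      if (anyNA(ord)) stop("JASPAR record missing a base row: ", header)
      counts <- do.call(rbind, lapply(vals[ord], `[[`, "nums"))
      name <- paste(hf, collapse = " ")
    } else {
      rows <- lapply(body, function(l)
        as.numeric(strsplit(trimws(l), "\\s+")[[1]]))
      nfield <- lengths(rows)
      if (all(nfield == 4) && length(rows) != 4) {
        counts <- t(do.call(rbind, rows))       # HOMER: rows = positions
        name <- if (length(hf) >= 2) hf[2] else hf[1]
      } else if (length(rows) == 4) {
        # bare JASPAR rows = bases; a 4x4 matrix is ambiguous and read as
        # JASPAR
        counts <- do.call(rbind, rows)
        name <- paste(hf, collapse = " ")
      } else {
        stop("unrecognized motif matrix layout for record: ", header)
      }
    }
    if (anyNA(counts)) stop("non-numeric motif matrix entry: ", header)
    probs <- normalize_counts(counts, pseudocount)
    motifs[[i]] <- new_pwm(name, probs)
  }
  motifs
}

#' Write motifs in JASPAR PFM style (probabilities scaled to counts)
#' @param motifs list of \code{pwm} objects.
#' @param path output file.
#' @param depth nominal count depth.
#' @export
write_motifs <- function(motifs, path, depth = 100) {
  out <- unlist(lapply(motifs, function(m) {
    mat <- round(m$matrix * depth, 4)
    c(paste0(">", m$name),
      vapply(seq_len(4), function(r)
        paste0(BASES[r], " [ ", paste(fmt_num(mat[r, ]), collapse = " "),
               " ]"), character(1)))
  }))
  writeLines(out, path)
  invisible(path)
}

seq_to_idx <- function(seq) {
  match(strsplit(toupper(seq), "", fixed = TRUE)[[1]], BASES)
}

# Scores of all length-L windows of an index vector under a log-odds
# matrix; windows containing N (NA index) score NA.
window_scores <- function(idx, lo) {
  L <- ncol(lo)
  W <- length(idx) - L + 1L
  if (W < 1L) return(numeric(0))
  pos <- outer(seq_len(W) - 1L, seq_len(L), "+")
  b <- idx[pos]
  sc <- matrix(lo[cbind(as.vector(b), rep(seq_len(L), each = W))],
               nrow = W)
  rowSums(sc)
}

#' Scan a sequence with a PWM
#'
#' Every window on both strands is scored by log2-odds
#' \code{sum_i log2(p_i(w_i) / bg(w_i))}; the minus strand is scored on the
#' reverse complement, with hit offsets reported in plus-strand
#' coordinates. A window is a hit when its score reaches
#' \code{threshold_frac} times the maximum achievable score. Windows
#' containing \code{N} are skipped.
#'
#' @param pwm a \code{pwm} object.
#' @param seq nucleotide string.
#' @param threshold_frac fraction of the maximal log-odds score required
#'   for a hit, in (0, 1] (default 0.8).
#' @param background base composition for the log-odds denominator;
#'   defaults to the PWM's stored background.
#' @param seq_id identifier copied into the hit table.
#' @return \code{data.frame(seq_id, offset, strand, score)} with 0-based
#'   offsets.
#' @export
scan_sequence <- function(pwm, seq, threshold_frac = 0.8,
                          background = pwm$background, seq_id = NA) {
  stopifnot(threshold_frac > 0, threshold_frac <= 1)
  lo <- log2(pwm$matrix / background)
  L <- ncol(lo)
  thr <- threshold_frac * pwm_max_score(pwm, background) - 1e-9
  idx <- seq_to_idx(seq)
  n <- length(idx)
  empty <- data.frame(seq_id = character(), offset = integer(),
                      strand = character(), score = numeric())
  if (n < L) return(empty)
  fwd <- window_scores(idx, lo)
  rev_idx <- rev(5L - idx)           # reverse complement in index space
  rvs <- window_scores(rev_idx, lo)
  hits_f <- which(!is.na(fwd) & fwd >= thr)
  hits_r <- which(!is.na(rvs) & rvs >= thr)
  out <- data.frame(
    seq_id = rep(as.character(seq_id), length(hits_f) + length(hits_r)),
    offset = c(hits_f - 1L, n - L + 1L - hits_r),
    strand = c(rep("+", length(hits_f)), rep("-", length(hits_r))),
    score = c(fwd[hits_f], rvs[hits_r])
  )
  out[order(out$offset, out$strand), , drop = FALSE]
}

# TRUE per sequence if the PWM has at least one hit.
sequences_with_hit <- function(pwm, seqs, threshold_frac = 0.8,
                               background = pwm$background) {
  vapply(seq_along(seqs), function(i)
    nrow(scan_sequence(pwm, seqs[[i]], threshold_frac, background)) > 0,
    logical(1))
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up rule: \code{adj_(i) = min_{j >= i} (m p_(j) / j)}, clipped at 1,
#' returned in input order.
#'
#' @param pvalues numeric vector of p-values in \code{[0, 1]}.
#' @return adjusted p-values.
#' @examples
#' bh_adjust(c(0.01, 0.02, 0.03))  # 0.03 0.03 0.03
#' @export
bh_adjust <- function(pvalues) {
  if (length(pvalues) == 0) return(numeric(0))
  if (any(is.na(pvalues)) || any(pvalues < 0 | pvalues > 1))
    stop("p-values must lie in [0, 1]")
  m <- length(pvalues)
  o <- order(pvalues)
  adj <- rev(cummin(rev(pvalues[o] * m / seq_len(m))))
  adj <- pmin(adj, 1)
  out <- numeric(m)
  out[o] <- adj
  out
}

#' Motif enrichment in target vs background sequences
#'
#' For each motif, counts target and background sequences carrying at
#' least one hit and scores enrichment with a hypergeometric upper tail:
#' with population \code{N = |T| + |B|}, \code{m = k + b} hit-carrying
#' sequences and \code{|T|} draws, \code{p = P(X >= k)}. In the intended
#' use the background is the common-class peak sequences. BH adjustment is
#' applied across motifs; results are sorted by ascending p with a
#' deterministic name tie-break.
#'
#' @param targets,background named character vectors of sequences; both
#'   must be non-empty.
#' @param motifs list of \code{pwm} objects.
#' @param threshold_frac hit threshold passed to [scan_sequence()].
#' @param background_composition base composition for log-odds scoring;
#'   default is the empirical A/C/G/T frequency of the combined input
#'   sequences.
#' @return \code{data.frame(motif, k, n_target, bg_hits, n_background,
#'   fold, p, fdr)} sorted by p.
#' @export
enrich_motifs <- function(targets, background, motifs,
                          threshold_frac = 0.8,
                          background_composition = NULL) {
  if (length(targets) == 0 || length(background) == 0)
    stop("target and background sets must be non-empty")
  if (is.null(background_composition)) {
    tab <- table(factor(unlist(strsplit(toupper(
      paste(c(targets, background), collapse = "")), "")), levels = BASES))
    background_composition <- (as.numeric(tab) + 1) / (sum(tab) + 4)
  }
  names(background_composition) <- BASES
  nT <- length(targets)
  nB <- length(background)
  rows <- lapply(motifs, function(m) {
    k <- sum(sequences_with_hit(m, targets, threshold_frac,
                                background_composition))
    b <- sum(sequences_with_hit(m, background, threshold_frac,
                                background_composition))
    p <- stats::phyper(k - 1, k + b, nT + nB - k - b, nT,
                       lower.tail = FALSE)
    fold <- if (b == 0) {
      if (k == 0) NA_real_ else Inf
    } else (k / nT) / (b / nB)
    data.frame(motif = m$name, k = k, n_target = nT, bg_hits = b,
               n_background = nB, fold = fold, p = p)
  })
  res <- do.call(rbind, rows)
  res$fdr <- bh_adjust(res$p)
  res <- res[order(res$p, res$motif), , drop = FALSE]
  rownames(res) <- NULL
  res
}

gc_fraction <- function(seqs) {
  vapply(seqs, function(s) {
    v <- strsplit(toupper(s), "", fixed = TRUE)[[1]]
    n <- sum(v %in% BASES)
    if (n == 0) return(NA_real_)
    sum(v %in% c("G", "C")) / n
  }, numeric(1), USE.NAMES = FALSE)
}

#' GC-matched background subsampling
#'
#' Resamples the background so its GC-content histogram over \code{bins}
#' equal-width bins matches the targets' histogram, guarding enrichment
#' against composition bias. Bins short of background sequences are drawn
#' with replacement (logged); bins with target mass but no background
#' sequences are skipped with a warning and the remaining mass is
#' renormalized.
#'
#' @param background,targets named character vectors of sequences.
#' @param bins number of equal-width GC bins over \code{[0, 1]}.
#' @param size output sample size; defaults to \code{length(background)}.
#' @param seed optional RNG seed for a reproducible subsample.
#' @return a named character vector of resampled background sequences.
#' @export
gc_matched_subsample <- function(background, targets, bins = 10,
                                 size = length(background), seed = NULL) {
  stopifnot(length(background) > 0, length(targets) > 0)
  with_seed(seed, {
    edges <- seq(0, 1, length.out = bins + 1)
    bin_of <- function(g) pmin(pmax(findInterval(g, edges,
                                                 rightmost.closed = TRUE),
                                    1L), bins)
    tb <- bin_of(gc_fraction(targets))
    bb <- bin_of(gc_fraction(background))
    prop <- tabulate(tb, nbins = bins) / length(tb)
    avail <- tabulate(bb, nbins = bins)
    dead <- prop > 0 & avail == 0
    if (any(dead)) {
      warning(sprintf("%d GC bin(s) with target mass have no background; skipped",
                      sum(dead)))
      prop[dead] <- 0
      if (sum(prop) == 0) stop("no GC bin overlap between targets and background")
      prop <- prop / sum(prop)
    }
    want <- round(prop * size)
    picks <- unlist(lapply(which(want > 0), function(bn) {
      pool <- which(bb == bn)
      replace <- want[bn] > length(pool)
      if (replace)
        message(sprintf("GC bin %d short (%d available, %d requested); sampling with replacement",
                        bn, length(pool), want[bn]))
      pool[sample.int(length(pool), want[bn], replace = replace)]
    }))
    background[picks]
  })
}
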