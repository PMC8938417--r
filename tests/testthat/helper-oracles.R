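# Independent oracles and fixture builders. Oracles deliberately avoid
# the package's own code paths: inline arithmetic, explicit loops, exact
# enumeration.

# gap between half-open intervals, inline arithmetic
oracle_distance <- function(c1, s1, e1, c2, s2, e2) {
  if (c1 != c2) return(NA_real_)
  if (s1 < e2 && s2 < e1) return(0)        # overlap
  if (e1 <= s2) s2 - e1 else s1 - e2       # gap (book-ended -> 0)
}

# exhaustive O(n^2) nearest-subject scan; ties: smaller start, then
# lexicographic name, then subject order
oracle_nearest <- function(query, subjects, max_gap = Inf) {
  nq <- nrow(query)
  out_q <- integer(nq)
  out_s <- integer(nq)
  out_d <- numeric(nq)
  found <- 0L
  for (i in seq_len(nq)) {
    best_j <- NA_integer_
    best_d <- Inf
    for (j in seq_len(nrow(subjects))) {
      d <- oracle_distance(query$chrom[i], query$start[i], query$end[i],
                           subjects$chrom[j], subjects$start[j],
                           subjects$end[j])
      if (is.na(d) || d > max_gap) next
      better <- d < best_d ||
        (d == best_d && !is.na(best_j) &&
           (subjects$start[j] < subjects$start[best_j] ||
              (subjects$start[j] == subjects$start[best_j] &&
                 !is.na(subjects$name[j]) &&
                 (is.na(subjects$name[best_j]) ||
                    subjects$name[j] < subjects$name[best_j]))))
      if (better) {
        best_j <- j
        best_d <- d
      }
    }
    if (!is.na(best_j)) {
      found <- found + 1L
      out_q[found] <- i
      out_s[found] <- best_j
      out_d[found] <- best_d
    }
  }
  idx <- seq_len(found)
  data.frame(query = out_q[idx], subject = out_s[idx],
             distance = out_d[idx])
}

random_interval_set <- function(n, n_chroms = 3, max_coord = 10000,
                                max_len = 300) {
  chrom <- paste0("chr", sample.int(n_chroms, n, replace = TRUE))
  start <- sample.int(max_coord, n, replace = TRUE) - 1
  len <- sample.int(max_len, n, replace = TRUE)
  genomic_intervals(chrom, start, start + len,
                    name = sprintf("iv%04d", seq_len(n)))
}

# brute-force basal-plus-extension domains: per-gene loop over all other
# genes, no sorting tricks
oracle_domains <- function(genes, basal_up, basal_down, max_ext,
                           chrom_lengths) {
  n <- nrow(genes)
  out <- data.frame(gene_id = genes$gene_id, start = NA_real_,
                    end = NA_real_, basal_start = NA_real_,
                    basal_end = NA_real_)
  for (i in seq_len(n)) {
    len <- chrom_lengths[[genes$chrom[i]]]
    tss <- genes$tss[i]
    if (genes$strand[i] == "+") {
      bs <- max(0, tss - basal_up); be <- min(len, tss + basal_down)
    } else {
      bs <- max(0, tss - basal_down); be <- min(len, tss + basal_up)
    }
    left <- 0
    right <- len
    for (j in seq_len(n)) {
      if (j == i || genes$chrom[j] != genes$chrom[i]) next
      if (genes$strand[j] == "+") {
        obs <- max(0, genes$tss[j] - basal_up)
        obe <- min(len, genes$tss[j] + basal_down)
      } else {
        obs <- max(0, genes$tss[j] - basal_down)
        obe <- min(len, genes$tss[j] + basal_up)
      }
      if (obe <= tss && obe > left) left <- obe
      if (obs >= tss && obs < right) right <- obs
    }
    out$start[i] <- min(bs, max(left, tss - max_ext))
    out$end[i] <- max(be, min(right, tss + max_ext))
    out$basal_start[i] <- bs
    out$basal_end[i] <- be
  }
  out
}

random_gene_layout <- function(n_genes, chrom_lengths) {
  chrom <- sample(names(chrom_lengths), n_genes, replace = TRUE)
  tss <- vapply(chrom, function(ch)
    sample.int(chrom_lengths[[ch]] - 2, 1), numeric(1))
  data.frame(gene_id = sprintf("g%03d", seq_len(n_genes)), chrom = chrom,
             tss = tss, strand = sample(c("+", "-"), n_genes, TRUE),
             tx_end = NA_real_, exon_starts = NA_character_,
             exon_ends = NA_character_, stringsAsFactors = FALSE,
             row.names = NULL)
}

# exact hypergeometric upper tail by combinatorial enumeration:
# population N, K marked, n drawn, P(X >= k)
oracle_hyper_upper <- function(k, K, N, n) {
  i <- max(k, 0):min(K, n)
  sum(choose(K, i) * choose(N - K, n - i)) / choose(N, n)
}

# per-window PWM rescoring with its own reverse complement and log-odds
# arithmetic
oracle_scan <- function(pwm, seq, threshold_frac, background) {
  bases <- c("A", "C", "G", "T")
  L <- ncol(pwm$matrix)
  chars <- strsplit(toupper(seq), "")[[1]]
  comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  rc <- rev(unname(comp[chars]))
  smax <- 0
  for (l in seq_len(L))
    smax <- smax + max(log2(pwm$matrix[, l] / background))
  thr <- threshold_frac * smax - 1e-9
  hits <- data.frame(offset = integer(), strand = character(),
                     score = numeric())
  score_at <- function(v, o) {
    s <- 0
    for (l in seq_len(L)) {
      b <- match(v[o + l], bases)
      if (is.na(b)) return(NA_real_)
      s <- s + log2(pwm$matrix[b, l] / background[b])
    }
    s
  }
  n <- length(chars)
  for (o in 0:(n - L)) {
    s <- score_at(chars, o)
    if (!is.na(s) && s >= thr)
      hits <- rbind(hits, data.frame(offset = o, strand = "+", score = s))
    s <- score_at(rc, o)
    if (!is.na(s) && s >= thr)
      hits <- rbind(hits, data.frame(offset = n - L - o, strand = "-",
                                     score = s))
  }
  hits[order(hits$offset, hits$strand), , drop = FALSE]
}

make_decoy_pwms <- function(n, L = 10) {
  lapply(seq_len(n), function(i) {
    consensus_pwm <- get("consensus_pwm", envir = asNamespace("flowreg"))
    consensus_pwm(sprintf("decoy_%02d", i),
                  paste(sample(c("A", "C", "G", "T"), L, TRUE),
                        collapse = ""))
  })
}

# Monte-Carlo expectation of the (direction, class) association cell
# under the generator's placement model: each class peak is targeted at
# a uniformly chosen direction-gene's domain with probability pi, else
# placed uniformly on the genome. Independent containment loop.
oracle_assoc_expectation <- function(domains, dir_gene_ids, n_peaks, pi,
                                     chrom_lengths, n_sim = 200) {
  dd <- domains[domains$gene_id %in% dir_gene_ids, , drop = FALSE]
  total <- sum(unlist(chrom_lengths))
  chroms <- names(chrom_lengths)
  cum <- cumsum(unlist(chrom_lengths))
  fracs <- numeric(n_sim)
  for (s in seq_len(n_sim)) {
    hit <- rep(FALSE, nrow(dd))
    for (p in seq_len(n_peaks)) {
      if (stats::runif(1) < pi) {
        hit[sample.int(nrow(dd), 1)] <- TRUE
      } else {
        pos <- stats::runif(1, 0, total)
        ci <- which(pos <= cum)[1]
        x <- pos - c(0, cum)[ci]
        on <- dd$chrom == chroms[ci] & dd$start <= x & x < dd$end
        hit[on] <- TRUE
      }
    }
    fracs[s] <- mean(hit)
  }
  100 * mean(fracs)
}
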