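# Independent brute-force oracles used to cross-check the implementation.
# These deliberately avoid the code paths (and the libraries) they verify.

# Benjamini-Hochberg step-up by the closed formula
bh_oracle <- function(p) {
  m <- length(p)
  ord <- order(p)
  q <- numeric(m)
  running <- 1
  for (i in rev(seq_len(m))) {
    running <- min(running, p[ord[i]] * m / i)
    q[ord[i]] <- running
  }
  q
}

# two-sided Fisher exact p by exhaustive enumeration of tables with fixed margins
fisher_oracle <- function(tab) {
  r1 <- sum(tab[1, ]); r2 <- sum(tab[2, ]); c1 <- sum(tab[, 1])
  a_range <- max(0, c1 - r2):min(r1, c1)
  probs <- vapply(a_range, function(a) dhyper(a, r1, r2, c1), numeric(1))
  obs <- dhyper(tab[1, 1], r1, r2, c1)
  sum(probs[probs <= obs * (1 + 1e-7)])
}

# largest connected component by flood fill over an adjacency list
lcc_oracle <- function(vertices, edge_a, edge_b) {
  adj <- lapply(stats::setNames(vector("list", length(vertices)), vertices),
                function(x) character())
  for (i in seq_along(edge_a)) {
    adj[[edge_a[i]]] <- c(adj[[edge_a[i]]], edge_b[i])
    adj[[edge_b[i]]] <- c(adj[[edge_b[i]]], edge_a[i])
  }
  seen <- character()
  best <- character()
  for (v in vertices) {
    if (v %in% seen) next
    comp <- character(); queue <- v
    while (length(queue)) {
      u <- queue[1]; queue <- queue[-1]
      if (u %in% comp) next
      comp <- c(comp, u)
      queue <- c(queue, setdiff(adj[[u]], comp))
    }
    seen <- c(seen, comp)
    comp <- sort(comp)
    if (length(comp) > length(best) ||
        (length(comp) == length(best) &&
         paste(comp, collapse = "\r") < paste(best, collapse = "\r")))
      best <- comp
  }
  best
}

# complete-linkage merge heights by O(n^3) recomputation on raw coordinates
complete_linkage_oracle <- function(x) {
  clusters <- as.list(seq_len(nrow(x)))
  d <- as.matrix(stats::dist(x))
  heights <- numeric(0)
  while (length(clusters) > 1) {
    best <- c(NA, NA); best_h <- Inf
    for (i in seq_along(clusters)) {
      for (j in seq_len(i - 1)) {
        h <- max(d[clusters[[i]], clusters[[j]]])
        if (h < best_h) { best_h <- h; best <- c(j, i) }
      }
    }
    heights <- c(heights, best_h)
    clusters[[best[1]]] <- c(clusters[[best[1]]], clusters[[best[2]]])
    clusters[[best[2]]] <- NULL
  }
  heights
}

# per-base replicate-consensus oracle on a small integer chromosome
consensus_oracle <- function(rep_intervals, chrom_len, min_support = 2) {
  # rep_intervals: list of data.frames (start, end), 1-based closed, one per rep
  cov <- integer(chrom_len)
  any_peak <- logical(chrom_len)
  for (df in rep_intervals) {
    hit <- logical(chrom_len)
    for (i in seq_len(nrow(df))) hit[df$start[i]:df$end[i]] <- TRUE
    cov <- cov + hit
    any_peak <- any_peak | hit
  }
  # merged spans = maximal runs of any_peak; retain spans holding a base with cov >= k
  r <- rle(any_peak)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  spans <- data.frame(start = starts[r$values], end = ends[r$values])
  keep <- vapply(seq_len(nrow(spans)), function(i)
    any(cov[spans$start[i]:spans$end[i]] >= min_support), logical(1))
  spans[keep, , drop = FALSE]
}

# exhaustive per-peak nearest-TSS classification on plain vectors
annotate_oracle <- function(anchors, chroms, tss_df, window = 3000) {
  # tss_df: data.frame(chrom, pos, strand, gene_id)
  n <- length(anchors)
  gene <- rep(NA_character_, n); dist <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    cand <- tss_df[tss_df$chrom == chroms[i], , drop = FALSE]
    if (!nrow(cand)) next
    signed <- anchors[i] - cand$pos
    signed[cand$strand == "-"] <- -signed[cand$strand == "-"]
    ord <- order(abs(signed), signed, cand$gene_id)
    gene[i] <- cand$gene_id[ord[1]]
    dist[i] <- signed[ord[1]]
  }
  list(gene = gene, distance = dist,
       is_target = !is.na(dist) & abs(dist) <= window)
}

# small helper: tissue-labelled matrix with two planted groups
tiny_two_group <- function(n_per = 3, delta = 2, sd = 0.1, n_probes = 5, seed = 1) {
  set.seed(seed)
  m <- matrix(rnorm(n_probes * 2 * n_per, 7, sd), n_probes,
              dimnames = list(sprintf("p%d", 1:n_probes),
                              sprintf("s%d", 1:(2 * n_per))))
  m[, 1:n_per] <- m[, 1:n_per] + delta
  sheet <- data.frame(sample_id = colnames(m),
                      tissue = rep(c("ATC", "DTC"), each = n_per),
                      study_id = "study1", stringsAsFactors = FALSE)
  list(matrix = m, sheet = sheet)
}
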