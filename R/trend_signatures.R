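# Core computation: per-comparison differential statistics, monotone trend
# classification across normal -> DTC -> ATC, the standardized fold-change
# (sFC) statistic, and the S1/S2/S3 signature partition.
#
# The three pairwise comparisons (DTC vs normal, ATC vs DTC, ATC vs normal)
# are each tested probe-wise with an equal-variance two-sided Student t and
# corrected with Benjamini-Hochberg. A gene enters a trend list only when at
# least one of its probes is significant in all three comparisons and the
# group means move monotonically; genes whose qualifying probes disagree in
# direction are excluded outright.

#' Probe-wise differential statistics for one two-group comparison
#'
#' Equal-variance two-sided Student t-test per probe, with log2 fold change
#' defined as `mean(class_a) - mean(class_b)` and Benjamini-Hochberg
#' adjustment across all probes of the comparison.
#'
#' @param m Expression matrix (probes x samples, log2).
#' @param sheet Sample sheet with `sample_id` and `tissue` columns.
#' @param class_a,class_b Tissue labels of the two groups (numerator first).
#' @return Data frame with columns `probe_id`, `log2fc`, `t`, `p`, `q` and a
#'   logical `zero_variance` flag (probes with zero pooled variance and
#'   equal means get `t = 0`, `p = 1` by convention).
#' @export
differential_probes <- function(m, sheet, class_a, class_b) {
  check_expression_matrix(m)
  if (!all(c("sample_id", "tissue") %in% names(sheet)))
    stop("sample sheet needs sample_id and tissue columns")
  a <- sheet$sample_id[sheet$tissue == class_a]
  b <- sheet$sample_id[sheet$tissue == class_b]
  a <- intersect(colnames(m), a)
  b <- intersect(colnames(m), b)
  if (length(a) < 2 || length(b) < 2)
    stop("each class needs >= 2 samples (", class_a, ": ", length(a),
         ", ", class_b, ": ", length(b), ")")
  xa <- m[, a, drop = FALSE]
  xb <- m[, b, drop = FALSE]
  na <- length(a); nb <- length(b)
  ma <- rowMeans(xa); mb <- rowMeans(xb)
  va <- rowSums((xa - ma)^2) / (na - 1)
  vb <- rowSums((xb - mb)^2) / (nb - 1)
  sp2 <- ((na - 1) * va + (nb - 1) * vb) / (na + nb - 2)
  se <- sqrt(sp2 * (1 / na + 1 / nb))
  fc <- ma - mb
  tt <- fc / se
  df <- na + nb - 2
  zero <- sp2 == 0
  tt[zero & fc == 0] <- 0
  p <- 2 * stats::pt(-abs(tt), df = df)
  p[zero & fc == 0] <- 1
  p[zero & fc != 0] <- 0
  data.frame(
    probe_id = rownames(m),
    log2fc = fc,
    t = tt,
    p = p,
    q = stats::p.adjust(p, method = "BH"),
    zero_variance = zero,
    row.names = NULL,
    stringsAsFactors = FALSE
  )
}

#' Classify genes into monotone expression trends
#'
#' A probe "qualifies" when its BH-adjusted p-value is below `alpha` in all
#' three comparisons. A qualifying probe's trend is Up when both step fold
#' changes (DTC vs normal, ATC vs DTC) are strictly positive, Down when both
#' are strictly negative, and no trend otherwise. A gene is labelled
#' `TrendUp`/`TrendDown` when its trended qualifying probes agree,
#' `excluded_discordant` when they disagree, and `not_deg` otherwise. The
#' representative probe is the qualifying probe (preferring probes of the
#' winning trend) with the smallest ATC-vs-DTC q, ties broken by probe id;
#' genes without qualifying probes fall back to their overall smallest-q
#' probe so that a fold change is defined for every gene.
#'
#' @param res_step1 `differential_probes()` result for DTC vs normal.
#' @param res_step2 Result for ATC vs DTC.
#' @param res_overall Result for ATC vs normal.
#' @param probe_map Data frame with `probe_id`, `gene_id`.
#' @param alpha Per-comparison adjusted-p significance cutoff (default 0.05).
#' @return Data frame with one row per gene: `gene_id`, `label` in
#'   `{TrendUp, TrendDown, excluded_discordant, not_deg}`, `probe_id`
#'   (representative), `log2fc_step1`, `log2fc_step2`.
#' @export
classify_trends <- function(res_step1, res_step2, res_overall, probe_map, alpha = 0.05) {
  for (r in list(res_step1, res_step2, res_overall)) {
    if (!all(c("probe_id", "log2fc", "q") %in% names(r)))
      stop("comparison results need probe_id, log2fc, q columns")
  }
  probes <- res_step1$probe_id
  if (!setequal(probes, res_step2$probe_id) || !setequal(probes, res_overall$probe_id))
    stop("the three comparisons must cover the same probes")
  missing <- setdiff(probes, probe_map$probe_id)
  if (length(missing))
    stop("probes absent from probe map: ", paste(utils::head(missing, 5), collapse = ", "))

  i2 <- match(probes, res_step2$probe_id)
  i3 <- match(probes, res_overall$probe_id)
  tab <- data.frame(
    probe_id = probes,
    gene_id = probe_map$gene_id[match(probes, probe_map$probe_id)],
    fc1 = res_step1$log2fc,
    fc2 = res_step2$log2fc[i2],
    q1 = res_step1$q,
    q2 = res_step2$q[i2],
    q3 = res_overall$q[i3],
    stringsAsFactors = FALSE
  )
  tab$qualifies <- tab$q1 < alpha & tab$q2 < alpha & tab$q3 < alpha
  tab$trend <- ifelse(tab$fc1 > 0 & tab$fc2 > 0, "up",
               ifelse(tab$fc1 < 0 & tab$fc2 < 0, "down", "none"))

  per_gene <- function(g) {
    qual <- g[g$qualifies, , drop = FALSE]
    trends <- unique(qual$trend[qual$trend != "none"])
    label <- if (nrow(qual) == 0L || length(trends) == 0L) {
      "not_deg"
    } else if (length(trends) > 1L) {
      "excluded_discordant"
    } else if (trends == "up") "TrendUp" else "TrendDown"
    # representative probe: prefer qualifying probes of the winning trend,
    # then any qualifying probe, then all probes; smallest step-2 q wins
    pool <- if (label %in% c("TrendUp", "TrendDown")) {
      qual[qual$trend == trends, , drop = FALSE]
    } else if (nrow(qual)) qual else g
    pool <- pool[order(pool$q2, pool$probe_id), , drop = FALSE]
    data.frame(
      gene_id = g$gene_id[1],
      label = label,
      probe_id = pool$probe_id[1],
      log2fc_step1 = pool$fc1[1],
      log2fc_step2 = pool$fc2[1],
      stringsAsFactors = FALSE
    )
  }
  parts <- lapply(split(tab, tab$gene_id), per_gene)
  out <- do.call(rbind, parts)
  out <- out[order(out$gene_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Standardize a vector of fold changes
#'
#' Centers and scales signed log2 fold changes over the standardization
#' population: `(FC - mean(FC)) / sd(FC)` with the n-1 sd.
#'
#' @param fc Numeric vector (length >= 2, non-constant), optionally named.
#' @return Numeric vector of sFC values, mean 0 and sd 1.
#' @export
standardize_fc <- function(fc) {
  if (length(fc) < 2) stop("need >= 2 fold changes to standardize")
  s <- stats::sd(fc)
  if (s == 0) stop("fold changes are constant; sd is zero")
  (fc - mean(fc)) / s
}

#' Signature cutoffs on the sFC scale
#'
#' @param lo Lower cutoff in standardized units (default 2).
#' @param hi Upper cutoff (default 4); must exceed `lo`.
#' @return List with `lo` and `hi`.
#' @export
signature_thresholds <- function(lo = 2, hi = 4) {
  if (!(lo > 0 && hi > lo)) stop("need 0 < lo < hi")
  list(lo = lo, hi = hi)
}

#' Partition trend genes into the S1/S2/S3 signatures
#'
#' Applies the printed sFC cutoffs to the two progression steps. For Up
#' genes: S1 when `sfc_step1 > hi` and `sfc_step2 < lo` (deregulated mainly
#' in the normal-to-DTC step), S2 when `sfc_step1 < lo` and `sfc_step2 > hi`
#' (mainly DTC-to-ATC), S3 when both exceed `lo` and neither S1 nor S2
#' applies. Down genes use the mirrored rules with negated cutoffs. All
#' inequalities are strict; precedence S1 > S2 > S3 makes the classes
#' mutually exclusive.
#'
#' @param trend_table Output of [classify_trends()].
#' @param sfc_step1,sfc_step2 Named numeric vectors of sFC values covering
#'   every trend gene (names are gene ids).
#' @param thr Cutoffs from [signature_thresholds()].
#' @return Data frame with `gene_id`, `direction` (`up`/`down`),
#'   `sfc_step1`, `sfc_step2`, `signature` in `{S1, S2, S3, unassigned}`,
#'   one row per trend gene, ordered by gene id.
#' @export
assign_signatures <- function(trend_table, sfc_step1, sfc_step2,
                              thr = signature_thresholds()) {
  keep <- trend_table$label %in% c("TrendUp", "TrendDown")
  tt <- trend_table[keep, , drop = FALSE]
  missing <- setdiff(tt$gene_id, intersect(names(sfc_step1), names(sfc_step2)))
  if (length(missing))
    stop("trend genes missing sFC values: ", paste(utils::head(missing, 5), collapse = ", "))
  s1 <- sfc_step1[tt$gene_id]
  s2 <- sfc_step2[tt$gene_id]
  up <- tt$label == "TrendUp"
  sig <- rep("unassigned", nrow(tt))
  # Up rules
  sig[up & s1 > thr$hi & s2 < thr$lo] <- "S1"
  sig[up & sig == "unassigned" & s1 < thr$lo & s2 > thr$hi] <- "S2"
  sig[up & sig == "unassigned" & s1 > thr$lo & s2 > thr$lo] <- "S3"
  # Down rules, mirrored
  dn <- !up
  sig[dn & s1 < -thr$hi & s2 > -thr$lo] <- "S1"
  sig[dn & sig == "unassigned" & s1 > -thr$lo & s2 < -thr$hi] <- "S2"
  sig[dn & sig == "unassigned" & s1 < -thr$lo & s2 < -thr$lo] <- "S3"
  out <- data.frame(
    gene_id = tt$gene_id,
    direction = ifelse(up, "up", "down"),
    sfc_step1 = unname(s1),
    sfc_step2 = unname(s2),
    signature = sig,
    stringsAsFactors = FALSE
  )
  out <- out[order(out$gene_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Hypergeometric over-representation test
#'
#' One-sided upper-tail hypergeometric test of a gene set against each
#' annotation set within a fixed universe, BH-corrected across sets.
#'
#' @param gene_set Character vector of genes (subset of `universe`).
#' @param annotation Named list of character vectors (each a subset of the
#'   universe).
#' @param universe Character vector of all considered genes.
#' @return Data frame with `set`, `size`, `overlap`, `expected`, `p`, `q`.
#' @export
enrichment_test <- function(gene_set, annotation, universe) {
  universe <- unique(universe)
  if (!length(universe)) stop("empty universe")
  if (!all(gene_set %in% universe)) stop("gene_set must be a subset of the universe")
  gene_set <- unique(gene_set)
  n <- length(gene_set)
  N <- length(universe)
  rows <- lapply(names(annotation), function(nm) {
    set <- unique(intersect(annotation[[nm]], universe))
    K <- length(set)
    k <- length(intersect(gene_set, set))
    data.frame(
      set = nm,
      size = K,
      overlap = k,
      expected = n * K / N,
      p = stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  out$q <- stats::p.adjust(out$p, method = "BH")
  rownames(out) <- NULL
  out
}
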