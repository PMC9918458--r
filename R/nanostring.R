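# NanoString-style validation: normalize raw panel counts against negative
# controls (background), positive controls (technical scale) and
# housekeeping genes (input amount), then reproduce the validation
# statistics: per-gene ATC-vs-DTC differential, matched-pair comparisons and
# percent-expressing. The qPCR delta-delta-Ct formula lives here too.

#' Construct a raw NanoString-style panel object
#'
#' @param counts Non-negative integer matrix, genes x samples, with
#'   dimnames.
#' @param gene_class Character vector (one per gene row) in
#'   `{Endogenous, Positive, Negative, Housekeeping}`.
#' @param samples Data frame with `sample_id`, `tissue` (`ATC`/`DTC`) and
#'   `patient_id`, one row per column of `counts`.
#' @return A `nanostring_raw` list.
#' @export
nanostring_raw <- function(counts, gene_class, samples) {
  if (!is.matrix(counts) || any(counts < 0)) stop("counts must be a non-negative matrix")
  if (length(gene_class) != nrow(counts)) stop("gene_class length must match rows")
  ok <- c("Endogenous", "Positive", "Negative", "Housekeeping")
  if (!all(gene_class %in% ok)) stop("invalid gene class")
  if (sum(gene_class == "Positive") < 1 || sum(gene_class == "Negative") < 1)
    stop("need at least one positive and one negative control")
  if (!all(c("sample_id", "tissue", "patient_id") %in% names(samples)))
    stop("samples needs sample_id, tissue, patient_id")
  if (!identical(colnames(counts), samples$sample_id))
    stop("sample sheet order must match count columns")
  structure(list(counts = counts, gene_class = gene_class, samples = samples),
            class = "nanostring_raw")
}

geo_mean <- function(x) exp(mean(log(x)))

#' Normalize NanoString-style raw counts
#'
#' Per sample: (1) background, estimated as mean + 2 sd of that sample's
#' negative controls, is subtracted and the result floored at 1 count;
#' (2) a technical scale factor from positive controls (grand geometric mean
#' across samples over the sample's geometric mean) is multiplied in;
#' (3) a content factor computed the same way from the housekeeping genes on
#' the positive-control-corrected values is multiplied in; (4) values are
#' log2 transformed. Computing the housekeeping factor after the positive
#' correction keeps the whole recipe invariant to a per-sample global scale.
#'
#' @param raw A [nanostring_raw()] object.
#' @return A `nanostring_norm` list with `log2` (endogenous +
#'   housekeeping genes x samples), `expressed` (logical matrix: counts
#'   above background floor), `background`, `pos_factor`, `hk_factor` and
#'   the `samples` sheet.
#' @export
normalize_nanostring <- function(raw) {
  stopifnot(inherits(raw, "nanostring_raw"))
  counts <- raw$counts
  cls <- raw$gene_class
  neg <- counts[cls == "Negative", , drop = FALSE]
  pos <- counts[cls == "Positive", , drop = FALSE]
  hk_rows <- which(cls == "Housekeeping")
  if (length(hk_rows) < 2) stop("need >= 2 housekeeping genes")
  dead <- colnames(counts)[colSums(pos) == 0 |
                           colSums(counts[hk_rows, , drop = FALSE]) == 0]
  if (length(dead)) stop("all-zero controls in sample(s): ", paste(dead, collapse = ", "))

  bg <- apply(neg, 2, function(x) mean(x) + 2 * stats::sd(x))
  sub <- sweep(counts, 2, bg, "-")
  expressed <- sub > 1
  sub <- pmax(sub, 1)

  pos_sub <- pmax(sweep(pos, 2, bg, "-"), 1)
  pos_gm <- apply(pos_sub, 2, geo_mean)
  pos_factor <- geo_mean(pos_gm) / pos_gm
  corrected <- sweep(sub, 2, pos_factor, "*")

  hk <- corrected[hk_rows, , drop = FALSE]
  hk_gm <- apply(hk, 2, geo_mean)
  hk_factor <- geo_mean(hk_gm) / hk_gm
  corrected <- sweep(corrected, 2, hk_factor, "*")

  keep <- cls %in% c("Endogenous", "Housekeeping")
  structure(list(
    log2 = log2(corrected[keep, , drop = FALSE]),
    expressed = expressed[keep, , drop = FALSE],
    gene_class = cls[keep],
    background = bg,
    pos_factor = pos_factor,
    hk_factor = hk_factor,
    samples = raw$samples
  ), class = "nanostring_norm")
}

#' Panel-wide ATC vs DTC differential test
#'
#' Two-sided equal-variance Student t per endogenous gene on normalized log2
#' values, BH-corrected across the panel. A gene is `validated` when
#' `q < alpha` and its ATC - DTC log2 fold change is positive.
#'
#' @param norm A `nanostring_norm` object.
#' @param alpha Adjusted-p cutoff for validation (default 0.05).
#' @return Data frame with `gene`, `log2fc`, `p`, `q`, `validated`.
#' @export
differential_panel <- function(norm, alpha = 0.05) {
  stopifnot(inherits(norm, "nanostring_norm"))
  tissue <- norm$samples$tissue
  if (sum(tissue == "ATC") < 2 || sum(tissue == "DTC") < 2)
    stop("need >= 2 samples per tissue")
  x <- norm$log2[norm$gene_class == "Endogenous", , drop = FALSE]
  sheet <- data.frame(sample_id = colnames(x), tissue = tissue,
                      stringsAsFactors = FALSE)
  res <- differential_probes(x, sheet, "ATC", "DTC")
  data.frame(
    gene = res$probe_id,
    log2fc = res$log2fc,
    p = res$p,
    q = res$q,
    validated = res$q < alpha & res$log2fc > 0,
    stringsAsFactors = FALSE
  )
}

#' Matched-pair ATC vs DTC comparison
#'
#' For patients with both components profiled, computes the per-patient
#' log2 difference per gene, its mean, a paired t-test p-value and the
#' fraction of pairs with a positive difference.
#'
#' @param norm A `nanostring_norm` object whose sample sheet contains, for
#'   every `patient_id` used, exactly one ATC and one DTC sample.
#' @param patients Optional subset of patient ids (default: all patients
#'   appearing with two samples).
#' @return Data frame with `gene`, `mean_delta`, `p`, `frac_positive`.
#' @export
paired_component_compare <- function(norm, patients = NULL) {
  stopifnot(inherits(norm, "nanostring_norm"))
  sheet <- norm$samples
  if (is.null(patients)) {
    tab <- table(sheet$patient_id)
    patients <- names(tab)[tab == 2L]
  }
  if (length(patients) < 2) stop("need >= 2 complete patient pairs")
  atc_idx <- dtc_idx <- integer(length(patients))
  for (i in seq_along(patients)) {
    rows <- which(sheet$patient_id == patients[i])
    a <- rows[sheet$tissue[rows] == "ATC"]
    d <- rows[sheet$tissue[rows] == "DTC"]
    if (length(a) != 1L || length(d) != 1L)
      stop("incomplete pair for patient ", patients[i])
    atc_idx[i] <- a; dtc_idx[i] <- d
  }
  x <- norm$log2[norm$gene_class == "Endogenous", , drop = FALSE]
  delta <- x[, atc_idx, drop = FALSE] - x[, dtc_idx, drop = FALSE]
  p <- apply(delta, 1, function(d) stats::t.test(d)$p.value)
  data.frame(
    gene = rownames(delta),
    mean_delta = rowMeans(delta),
    p = unname(p),
    frac_positive = rowMeans(delta > 0),
    stringsAsFactors = FALSE
  )
}

#' Percentage of samples expressing each gene, per tissue
#'
#' A sample expresses a gene when its background-subtracted count exceeded
#' the floor during normalization.
#'
#' @param norm A `nanostring_norm` object.
#' @return Data frame with `gene`, `pct_atc`, `pct_dtc` (one decimal).
#' @export
percent_expressing <- function(norm) {
  stopifnot(inherits(norm, "nanostring_norm"))
  ex <- norm$expressed[norm$gene_class == "Endogenous", , drop = FALSE]
  tissue <- norm$samples$tissue
  pct <- function(cols) {
    if (!sum(cols)) return(rep(NA_real_, nrow(ex)))
    proportion_pct(rowSums(ex[, cols, drop = FALSE]), sum(cols), digits = 1)
  }
  data.frame(
    gene = rownames(ex),
    pct_atc = pct(tissue == "ATC"),
    pct_dtc = pct(tissue == "DTC"),
    stringsAsFactors = FALSE
  )
}

#' Relative expression by the delta-delta-Ct method
#'
#' `relative = 2^-((Ct_gene - Ct_ref)_condition - (Ct_gene - Ct_ref)_control)`;
#' the control condition is 1 by construction.
#'
#' @param ct Data frame with `condition`, `gene`, `ct` (cycle thresholds).
#' @param reference_gene Reference gene id (e.g. actin), measured in every
#'   condition.
#' @param control_condition Baseline condition label.
#' @return Data frame with `condition`, `gene`, `relative_expression`.
#' @export
ddct <- function(ct, reference_gene, control_condition) {
  stopifnot(all(c("condition", "gene", "ct") %in% names(ct)))
  conds <- unique(ct$condition)
  if (!control_condition %in% conds) stop("control condition absent")
  ref <- ct[ct$gene == reference_gene, , drop = FALSE]
  if (!all(conds %in% ref$condition))
    stop("reference gene missing in condition(s): ",
         paste(setdiff(conds, ref$condition), collapse = ", "))
  ref_ct <- stats::setNames(ref$ct, ref$condition)
  genes <- ct[ct$gene != reference_gene, , drop = FALSE]
  genes$dct <- genes$ct - ref_ct[genes$condition]
  ctrl <- genes[genes$condition == control_condition, , drop = FALSE]
  ctrl_dct <- stats::setNames(ctrl$dct, ctrl$gene)
  if (!all(genes$gene %in% names(ctrl_dct)))
    stop("gene(s) missing in control condition")
  genes$relative_expression <- 2^(-(genes$dct - ctrl_dct[genes$gene]))
  genes[, c("condition", "gene", "relative_expression")]
}
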