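# Orchestration: compose the signature stages (normalize -> differential ->
# trends -> sFC -> signatures -> network module) and the regulome stages
# (consensus peaks -> TSS targets -> DEG thresholding -> core program), plus
# the planted-truth evaluation used by the package's benchmarks.

#' Pipeline configuration
#'
#' Collects the printed analysis settings with their defaults: adjusted-p
#' cutoff 0.05 for the three comparisons, sFC cutoffs 2/4, TSS window
#' +/- 3000 bp, replicate consensus support 2, DEG FDR 0.05, STRING-style
#' edge confidence 0.4.
#'
#' @param alpha Adjusted-p significance cutoff per comparison.
#' @param lo,hi sFC cutoffs (see [signature_thresholds()]).
#' @param sfc_population Standardization population for the sFC statistic:
#'   `"all"` (every gene with a fold change, the default) or `"trend"`
#'   (trend genes only).
#' @param min_score Minimum interaction-edge confidence.
#' @param tss_window TSS window half-width in bp.
#' @param min_support Minimum replicate support for a consensus peak.
#' @param fdr DEG q-value cutoff.
#' @param seed Integer seed for any stochastic step.
#' @return A named list.
#' @export
pipeline_config <- function(alpha = 0.05, lo = 2, hi = 4,
                            sfc_population = c("all", "trend"),
                            min_score = 0.4, tss_window = 3000,
                            min_support = 2, fdr = 0.05, seed = 1) {
  stopifnot(alpha > 0, tss_window > 0, min_support > 0, fdr > 0)
  list(alpha = alpha, thresholds = signature_thresholds(lo, hi),
       sfc_population = match.arg(sfc_population), min_score = min_score,
       tss_window = tss_window, min_support = min_support, fdr = fdr,
       seed = seed)
}

#' Derive trend signatures from an expression matrix
#'
#' Runs the full signature derivation on in-memory objects: quantile
#' normalization (optional), the three pairwise comparisons (DTC vs normal,
#' ATC vs DTC, ATC vs normal), monotone trend classification, per-comparison
#' sFC standardization and the S1/S2/S3 assignment.
#'
#' @param m Log2 expression matrix (probes x samples).
#' @param sheet Sample sheet (`sample_id`, `tissue`, `study_id`).
#' @param probe_map Data frame `probe_id`, `gene_id`.
#' @param config A [pipeline_config()].
#' @param exclude Optional sample ids to drop before analysis.
#' @param normalize Quantile-normalize first (default TRUE).
#' @return List with `comparisons` (the three stat tables), `trend_table`,
#'   `signatures` (per trend gene), and `counts` (per-stage summary).
#' @export
derive_signatures <- function(m, sheet, probe_map, config = pipeline_config(),
                              exclude = NULL, normalize = TRUE) {
  check_sample_sheet(sheet, m)
  if (length(exclude)) {
    red <- exclude_samples(m, sheet, exclude)
    m <- red$matrix; sheet <- red$sheet
  }
  if (normalize) m <- quantile_normalize(m)
  cmp <- list(
    step1 = differential_probes(m, sheet, "DTC", "NORM"),
    step2 = differential_probes(m, sheet, "ATC", "DTC"),
    overall = differential_probes(m, sheet, "ATC", "NORM")
  )
  trend <- classify_trends(cmp$step1, cmp$step2, cmp$overall, probe_map,
                           alpha = config$alpha)
  pop <- if (config$sfc_population == "all") rep(TRUE, nrow(trend)) else
    trend$label %in% c("TrendUp", "TrendDown")
  if (sum(pop) < 2) stop("sFC standardization population has < 2 genes")
  sfc1 <- stats::setNames(rep(NA_real_, nrow(trend)), trend$gene_id)
  sfc2 <- sfc1
  sfc1[pop] <- standardize_fc(trend$log2fc_step1[pop])
  sfc2[pop] <- standardize_fc(trend$log2fc_step2[pop])
  sigs <- assign_signatures(trend, sfc1, sfc2, thr = config$thresholds)
  counts <- list(
    n_samples = ncol(m),
    n_probes = nrow(m),
    n_genes = length(unique(probe_map$gene_id)),
    trend_up = sum(trend$label == "TrendUp"),
    trend_down = sum(trend$label == "TrendDown"),
    excluded_discordant = sum(trend$label == "excluded_discordant"),
    signature_sizes = table(paste(sigs$direction, sigs$signature, sep = "_"))
  )
  list(comparisons = cmp, trend_table = trend, signatures = sigs,
       counts = counts)
}

#' Extract the gene module for a signature selection
#'
#' Maps the selected signature genes into the interaction network and takes
#' the largest connected component.
#'
#' @param signatures Signature table from [derive_signatures()].
#' @param edges Edge data frame (`gene_a`, `gene_b`, `score`).
#' @param select Which (direction, signature) cells to map; default the Up
#'   S2 + S3 selection used for the disease module.
#' @param config A [pipeline_config()] (supplies `min_score`).
#' @return List with `module` (member gene ids), `mapped`, `unmapped`,
#'   `fraction` (percent of mapped genes in the module) and `graph`.
#' @export
extract_module <- function(signatures, edges,
                           select = list(direction = "up", signature = c("S2", "S3")),
                           config = pipeline_config()) {
  genes <- signatures$gene_id[
    signatures$direction %in% select$direction &
      signatures$signature %in% select$signature]
  net <- map_to_network(genes, edges, min_score = config$min_score)
  lcc <- largest_connected_component(net$graph)
  fraction <- if (length(net$mapped)) module_fraction(lcc$members, net$mapped) else NA_real_
  list(module = lcc$members, mapped = net$mapped, unmapped = net$unmapped,
       fraction = fraction, graph = lcc$graph)
}

#' Run the signature pipeline from files
#'
#' File-level wrapper: reads the expression matrix, sample sheet, probe map
#' and (optionally) an edge list, derives signatures and the module, and
#' writes `signatures.tsv`, `trend_table.tsv`, `module.tsv` and
#' `report.json` into `out_dir`.
#'
#' @param expression,sheet,probe_map,edges Input file paths (`edges`
#'   optional).
#' @param out_dir Output directory (created if missing).
#' @param config A [pipeline_config()].
#' @param exclude Sample ids to drop.
#' @return The result of [derive_signatures()] plus `module`, invisibly.
#' @export
run_signature_pipeline <- function(expression, sheet, probe_map, edges = NULL,
                                   out_dir = ".", config = pipeline_config(),
                                   exclude = NULL) {
  for (f in c(expression, sheet, probe_map, edges))
    if (!file.exists(f)) stop("input file not found: ", f)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  res <- derive_signatures(read_expression_tsv(expression),
                           read_sample_sheet(sheet),
                           read_probe_map(probe_map),
                           config = config, exclude = exclude)
  mod <- NULL
  if (!is.null(edges)) {
    mod <- extract_module(res$signatures, read_edge_list(edges), config = config)
    write_tsv(data.frame(gene_id = mod$module), file.path(out_dir, "module.tsv"))
  }
  write_tsv(res$trend_table, file.path(out_dir, "trend_table.tsv"))
  write_tsv(res$signatures, file.path(out_dir, "signatures.tsv"))
  report <- list(
    parameters = list(alpha = config$alpha, lo = config$thresholds$lo,
                      hi = config$thresholds$hi,
                      sfc_population = config$sfc_population,
                      min_score = config$min_score),
    counts = res$counts[c("n_samples", "n_probes", "n_genes", "trend_up",
                          "trend_down", "excluded_discordant")],
    signature_sizes = as.list(res$counts$signature_sizes),
    module_size = if (is.null(mod)) NULL else length(mod$module),
    module_fraction = if (is.null(mod)) NULL else mod$fraction
  )
  jsonlite::write_json(report, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  res$module <- mod
  invisible(res)
}

#' Run the regulome pipeline from files
#'
#' Reads per-replicate peak files, a GTF gene model and two DEG tables;
#' computes consensus peaks, TSS-window targets, thresholded DEG sets and
#' the three-way core program; writes `consensus.bed`, `annotation.tsv`,
#' `distribution.tsv`, `core_program.tsv` and `venn.json` into `out_dir`.
#'
#' @param peak_files Character vector of >= 2 replicate peak paths
#'   (BED6/narrowPeak).
#' @param gtf Gene model GTF path.
#' @param deg_a,deg_b DEG table TSV paths.
#' @param out_dir Output directory.
#' @param config A [pipeline_config()].
#' @return List with `consensus`, `annotation`, `targets`, `distribution`,
#'   `core`, invisibly.
#' @export
run_core_pipeline <- function(peak_files, gtf, deg_a, deg_b, out_dir = ".",
                              config = pipeline_config()) {
  for (f in c(peak_files, gtf, deg_a, deg_b))
    if (!file.exists(f)) stop("input file not found: ", f)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  reps <- lapply(seq_along(peak_files), function(i)
    read_peaks(peak_files[i], replicate_id = sprintf("rep%d", i)))
  model <- read_gene_model_gtf(gtf)
  cons <- consensus_peaks(reps, min_support = config$min_support)
  ann <- assign_peaks_to_genes(cons, model, tss_window = config$tss_window)
  dist <- genomic_distribution(cons, model, tss_window = config$tss_window)
  set_a <- threshold_deg(read_deg_table(deg_a), fdr = config$fdr)
  set_b <- threshold_deg(read_deg_table(deg_b), fdr = config$fdr)
  core <- core_program(set_a, set_b, ann$targets)
  write_peaks_bed(cons, file.path(out_dir, "consensus.bed"))
  write_tsv(ann$annotation, file.path(out_dir, "annotation.tsv"))
  write_tsv(dist, file.path(out_dir, "distribution.tsv"))
  write_tsv(data.frame(gene_id = core$core), file.path(out_dir, "core_program.tsv"))
  jsonlite::write_json(as.list(core$venn), file.path(out_dir, "venn.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(list(consensus = cons, annotation = ann$annotation,
                 targets = ann$targets, distribution = dist, core = core))
}

#' Evaluate planted-truth recovery of a signature run
#'
#' Compares a [derive_signatures()] result with the generator truth table.
#' Both headline metrics are conditioned on recovery (a planted gene is
#' "recovered" when it lands in a trend list): planted archetypes whose
#' effect is confined to one progression step have an exactly-zero effect in
#' one of the three mandatory comparisons and so cannot, by construction,
#' satisfy the all-three-significant rule.
#'
#' @param result Output of [derive_signatures()].
#' @param truth Truth table from [gen_multistudy_expression()].
#' @return List: `n_planted`, `n_recovered`, `direction_sensitivity`
#'   (recovered planted genes with the planted direction), and
#'   `archetype_accuracy` (recovered planted genes assigned their planted
#'   archetype), plus `n_false_trend` (non-planted genes in a trend list).
#' @export
evaluate_signature_recovery <- function(result, truth) {
  trend <- result$trend_table
  sigs <- result$signatures
  in_trend <- trend$label %in% c("TrendUp", "TrendDown")
  trend_genes <- trend$gene_id[in_trend]
  rec <- truth[truth$gene_id %in% trend_genes, , drop = FALSE]
  dir_of <- stats::setNames(ifelse(trend$label == "TrendUp", "up", "down"),
                            trend$gene_id)
  sig_of <- stats::setNames(sigs$signature, sigs$gene_id)
  n_rec <- nrow(rec)
  list(
    n_planted = nrow(truth),
    n_recovered = n_rec,
    direction_sensitivity = if (n_rec) mean(dir_of[rec$gene_id] == rec$direction) else NA_real_,
    archetype_accuracy = if (n_rec) mean(sig_of[rec$gene_id] == rec$archetype) else NA_real_,
    n_false_trend = sum(!trend_genes %in% truth$gene_id)
  )
}

#' Write a complete synthetic signature-pipeline input bundle
#'
#' Generates the expression matrix, sample sheet, probe map, edge list and
#' truth table for one seed and writes them as plain-text files into a
#' directory. The interaction network plants the Up S2+S3 genes as a
#' connected module among a gene background.
#'
#' @param dir Output directory.
#' @param config A [synth_expression_config()].
#' @param n_background Background genes in the interaction network.
#' @return Named list of written paths, invisibly.
#' @export
write_synthetic_bundle <- function(dir, config = synth_expression_config(),
                                   n_background = 160) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  sim <- gen_multistudy_expression(config)
  module_genes <- sim$truth$gene_id[sim$truth$direction == "up" &
                                      sim$truth$archetype %in% c("S2", "S3")]
  background <- setdiff(unique(sim$probe_map$gene_id), module_genes)
  background <- utils::head(background, n_background)
  edges <- gen_interaction_network(module_genes, background,
                                   seed = config$seed + 1L)
  paths <- list(
    expression = file.path(dir, "expression.tsv"),
    sheet = file.path(dir, "samples.tsv"),
    probe_map = file.path(dir, "probe_map.tsv"),
    edges = file.path(dir, "edges.tsv"),
    truth = file.path(dir, "truth.json")
  )
  write_expression_tsv(sim$matrix, paths$expression)
  write_tsv(sim$sheet, paths$sheet)
  write_tsv(sim$probe_map, paths$probe_map)
  write_tsv(edges, paths$edges)
  jsonlite::write_json(sim$truth, paths$truth, auto_unbox = TRUE, pretty = TRUE)
  invisible(paths)
}
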