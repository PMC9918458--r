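# Synthetic-data generators with planted truth. Every pipeline input can be
# produced at desk scale with known ground truth: a multi-study log2
# expression matrix with planted monotone effects for the S1/S2/S3
# archetypes, a planted interaction-network module, replicate-reproducible
# vs spurious ChIP peaks, two knockdown DEG tables sharing a planted core,
# and NanoString-style raw counts with controls.
#
# Noise model: Gaussian on the log2 scale for microarray-like data (matches
# RMA-style output); log-normal multiplicative noise on rounded counts for
# the NanoString generator. Batch effects are additive per-study offsets
# shared by all probes. All generators are bit-reproducible under a seed.

#' Configuration for the multi-study expression generator
#'
#' Defaults emulate the meta-dataset modelled by the package: 127 normal,
#' 102 differentiated-carcinoma and 50 anaplastic profiles pooled from 8
#' studies, with 20 genes planted per archetype per direction among 2000
#' genes.
#'
#' @param n_norm,n_dtc,n_atc Samples per tissue class.
#' @param n_studies Number of studies; samples are assigned round-robin
#'   within each class so classes stay balanced across studies.
#' @param n_genes Total genes.
#' @param planted Data frame with `gene` (index in `1..n_genes`),
#'   `direction` (`up`/`down`), `archetype` (`S1`/`S2`/`S3`),
#'   `effect_step1`, `effect_step2` (log2 units); see [default_planted()].
#' @param within_sd Within-class Gaussian noise sd (log2 units).
#' @param batch_sd Sd of the per-study additive offset.
#' @param probe_multiplicity Named probability vector over probes-per-gene
#'   counts `1`, `2`, `3`.
#' @param discordant_frac Fraction of multi-probe planted genes whose last
#'   probe gets a sign-flipped effect (triggering the discordance
#'   exclusion downstream).
#' @param baseline_mean,baseline_sd Per-probe log2 baseline distribution.
#' @param seed Integer seed.
#' @return A `synth_expression_config` list.
#' @export
synth_expression_config <- function(n_norm = 127, n_dtc = 102, n_atc = 50,
                                    n_studies = 8, n_genes = 2000,
                                    planted = default_planted(),
                                    within_sd = 0.5, batch_sd = 0.3,
                                    probe_multiplicity = c(`1` = 0.7, `2` = 0.2, `3` = 0.1),
                                    discordant_frac = 0.1,
                                    baseline_mean = 7, baseline_sd = 1,
                                    seed = 1) {
  stopifnot(n_norm > 0, n_dtc > 0, n_atc > 0, n_studies > 0, n_genes > 0,
            within_sd >= 0, batch_sd >= 0,
            discordant_frac >= 0, discordant_frac <= 1)
  if (!is.null(planted) && nrow(planted)) {
    req <- c("gene", "direction", "archetype", "effect_step1", "effect_step2")
    if (!all(req %in% names(planted))) stop("planted needs columns: ", paste(req, collapse = ", "))
    if (anyDuplicated(planted$gene)) stop("planted gene ids must be unique")
    if (any(planted$gene < 1 | planted$gene > n_genes))
      stop("planted gene index outside 1..n_genes")
    if (!all(planted$direction %in% c("up", "down"))) stop("invalid planted direction")
    if (!all(planted$archetype %in% c("S1", "S2", "S3"))) stop("invalid planted archetype")
  }
  if (abs(sum(probe_multiplicity) - 1) > 1e-8) stop("probe_multiplicity must sum to 1")
  structure(list(
    n_norm = n_norm, n_dtc = n_dtc, n_atc = n_atc, n_studies = n_studies,
    n_genes = n_genes, planted = planted, within_sd = within_sd,
    batch_sd = batch_sd, probe_multiplicity = probe_multiplicity,
    discordant_frac = discordant_frac, baseline_mean = baseline_mean,
    baseline_sd = baseline_sd, seed = seed
  ), class = "synth_expression_config")
}

#' Default planted-effect table
#'
#' Plants `n_per_group` genes per archetype per direction with the step
#' effects used throughout the package's benchmarks: S1 acts only in the
#' normal-to-DTC step, S2 only in the DTC-to-ATC step, S3 in both.
#'
#' @param n_per_group Genes per (archetype, direction) cell (default 20).
#' @param effects Named list of `c(effect_step1, effect_step2)` per
#'   archetype in log2 units.
#' @return Data frame consumable by [synth_expression_config()]; planted
#'   genes take the first indices.
#' @export
default_planted <- function(n_per_group = 20,
                            effects = list(S1 = c(2, 0), S2 = c(0, 2),
                                           S3 = c(1.5, 1.5))) {
  grid <- expand.grid(direction = c("up", "down"),
                      archetype = names(effects),
                      stringsAsFactors = FALSE)
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    e <- effects[[grid$archetype[i]]]
    data.frame(direction = grid$direction[i], archetype = grid$archetype[i],
               effect_step1 = e[1], effect_step2 = e[2],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows[rep(seq_along(rows), each = n_per_group)])
  out <- data.frame(gene = seq_len(nrow(out)), out, stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Generate a multi-study expression matrix with planted trends
#'
#' Probe values are class baseline + cumulative planted effect + per-study
#' batch offset + Gaussian noise. Cumulative effects by archetype (up
#' direction; down is negated): S1 adds `effect_step1` at DTC and nothing
#' more at ATC; S2 adds nothing at DTC and `effect_step2` at ATC; S3 adds
#' both steps. Discordant probes get the planted effect with flipped sign.
#'
#' @param config A [synth_expression_config()].
#' @return List with `matrix` (probes x samples, log2), `sheet` (sample
#'   sheet), `probe_map` (`probe_id`, `gene_id`) and `truth` (per planted
#'   gene: direction, archetype, discordant flag).
#' @export
gen_multistudy_expression <- function(config) {
  stopifnot(inherits(config, "synth_expression_config"))
  set.seed(config$seed)
  ng <- config$n_genes
  genes <- sprintf("g%04d", seq_len(ng))

  mult <- sample(as.integer(names(config$probe_multiplicity)), ng,
                 replace = TRUE, prob = config$probe_multiplicity)
  probe_map <- data.frame(
    probe_id = unlist(lapply(seq_len(ng), function(i)
      sprintf("%s_p%d", genes[i], seq_len(mult[i])))),
    gene_id = rep(genes, mult),
    stringsAsFactors = FALSE
  )
  np <- nrow(probe_map)

  classes <- c(rep("NORM", config$n_norm), rep("DTC", config$n_dtc),
               rep("ATC", config$n_atc))
  sheet <- data.frame(
    sample_id = sprintf("%s_%03d", tolower(classes),
                        unlist(lapply(c(config$n_norm, config$n_dtc, config$n_atc), seq_len))),
    tissue = classes,
    study_id = sprintf("study%d",
                       unlist(lapply(c(config$n_norm, config$n_dtc, config$n_atc),
                                     function(n) ((seq_len(n) - 1) %% config$n_studies) + 1))),
    stringsAsFactors = FALSE
  )

  baseline <- stats::rnorm(np, config$baseline_mean, config$baseline_sd)

  # per-probe cumulative effect at DTC and at ATC
  eff_dtc <- eff_atc <- numeric(np)
  truth <- data.frame(gene_id = character(), direction = character(),
                      archetype = character(), discordant = logical(),
                      stringsAsFactors = FALSE)
  planted <- config$planted
  if (!is.null(planted) && nrow(planted)) {
    planted$gene_id <- genes[planted$gene]
    multi <- planted$gene_id[mult[planted$gene] >= 2L]
    n_disc <- round(config$discordant_frac * length(multi))
    disc <- if (n_disc > 0) sample(multi, n_disc) else character()
    planted$discordant <- planted$gene_id %in% disc
    for (i in seq_len(nrow(planted))) {
      sign <- if (planted$direction[i] == "up") 1 else -1
      d <- switch(planted$archetype[i],
                  S1 = c(planted$effect_step1[i], planted$effect_step1[i]),
                  S2 = c(0, planted$effect_step2[i]),
                  S3 = c(planted$effect_step1[i],
                         planted$effect_step1[i] + planted$effect_step2[i]))
      rows <- which(probe_map$gene_id == planted$gene_id[i])
      flip <- rep(1, length(rows))
      if (planted$discordant[i]) flip[length(rows)] <- -1
      eff_dtc[rows] <- sign * d[1] * flip
      eff_atc[rows] <- sign * d[2] * flip
    }
    truth <- planted[, c("gene_id", "direction", "archetype", "discordant")]
  }

  batch <- stats::rnorm(config$n_studies, 0, config$batch_sd)
  names(batch) <- sprintf("study%d", seq_len(config$n_studies))

  class_eff <- rbind(NORM = numeric(np), DTC = eff_dtc, ATC = eff_atc)
  m <- matrix(0, np, nrow(sheet),
              dimnames = list(probe_map$probe_id, sheet$sample_id))
  noise <- matrix(stats::rnorm(np * nrow(sheet), 0, config$within_sd),
                  np, nrow(sheet))
  for (j in seq_len(nrow(sheet))) {
    m[, j] <- baseline + class_eff[sheet$tissue[j], ] +
      batch[sheet$study_id[j]] + noise[, j]
  }
  list(matrix = m, sheet = sheet, probe_map = probe_map, truth = truth)
}

#' Generate an interaction network with a planted module
#'
#' Erdos-Renyi-style edges: pairs within the module appear with probability
#' `p_within`, every other pair (background-background and module-background)
#' with `p_background`. Edge confidence scores are drawn uniformly in
#' `[0.4, 1]`.
#'
#' @param module_genes,background_genes Disjoint character vectors.
#' @param p_within,p_background Edge probabilities in `[0, 1]`.
#' @param seed Integer seed.
#' @return Edge data frame (`gene_a`, `gene_b`, `score`).
#' @export
gen_interaction_network <- function(module_genes, background_genes,
                                    p_within = 0.8, p_background = 0.01,
                                    seed = 1) {
  if (length(intersect(module_genes, background_genes)))
    stop("module and background gene lists must be disjoint")
  stopifnot(p_within >= 0, p_within <= 1, p_background >= 0, p_background <= 1)
  set.seed(seed)
  all_genes <- c(module_genes, background_genes)
  if (length(all_genes) < 2)
    return(data.frame(gene_a = character(), gene_b = character(),
                      score = numeric(), stringsAsFactors = FALSE))
  pairs <- utils::combn(all_genes, 2)
  in_module <- pairs[1, ] %in% module_genes & pairs[2, ] %in% module_genes
  p <- ifelse(in_module, p_within, p_background)
  keep <- stats::runif(ncol(pairs)) < p
  data.frame(
    gene_a = pairs[1, keep],
    gene_b = pairs[2, keep],
    score = round(stats::runif(sum(keep), 0.4, 1), 3),
    stringsAsFactors = FALSE
  )
}

#' Generate a toy gene model
#'
#' Places non-overlapping transcripts (one per gene, >= 2 exons each, both
#' strands unless forced) in evenly sized slots along each chromosome, with
#' short terminal UTRs, leaving intergenic room for distal noise peaks.
#'
#' @param n_genes Number of genes.
#' @param n_chroms Number of chromosomes (named `chr1..`).
#' @param chrom_len Chromosome length in bp.
#' @param seed Integer seed.
#' @param gene_width Range of transcript widths.
#' @param strand Optional fixed strand (`"+"` or `"-"`); default random.
#' @param utr_len Length of each terminal UTR (default 200 bp).
#' @return A [gene_model()].
#' @export
gen_gene_model <- function(n_genes, n_chroms = 2, chrom_len = 1e6, seed = 1,
                           gene_width = c(3000, 8000), strand = NULL,
                           utr_len = 200) {
  set.seed(seed)
  per_chrom <- rep(ceiling(n_genes / n_chroms), n_chroms)
  per_chrom[n_chroms] <- n_genes - sum(per_chrom[-n_chroms])
  slot <- floor(chrom_len / max(per_chrom))
  margin <- 8000  # intergenic room for TSS windows and distal noise peaks
  if (slot < gene_width[2] + 2 * margin)
    stop("infeasible packing: ", n_genes, " genes of width <= ", gene_width[2],
         " do not fit in ", n_chroms, " chromosome(s) of ", chrom_len, " bp")
  tx_list <- ex_list <- u5_list <- u3_list <- list()
  gi <- 0L
  for (ch in seq_len(n_chroms)) {
    for (s in seq_len(per_chrom[ch])) {
      gi <- gi + 1L
      gid <- sprintf("gene%03d", gi)
      tid <- paste0(gid, "_t1")
      w <- round(stats::runif(1, gene_width[1], gene_width[2]))
      start <- (s - 1L) * slot + margin +
        round(stats::runif(1, 0, slot - w - 2 * margin))
      end <- start + w - 1L
      str <- if (is.null(strand)) sample(c("+", "-"), 1) else strand
      chrom <- paste0("chr", ch)
      tx_list[[gi]] <- data.frame(chrom = chrom, start = start, end = end,
                                  strand = str, gene_id = gid,
                                  transcript_id = tid, stringsAsFactors = FALSE)
      # 2-4 exons: cut the body at interior points, alternate exon/intron
      n_ex <- sample(2:4, 1)
      cuts <- sort(round(stats::runif(2 * (n_ex - 1), start + 300, end - 300)))
      bounds <- c(start, cuts, end)
      ex_start <- bounds[seq(1, length(bounds), by = 2)]
      ex_end <- bounds[seq(2, length(bounds), by = 2)]
      ex_list[[gi]] <- data.frame(chrom = chrom, start = ex_start, end = ex_end,
                                  strand = str, gene_id = gid, transcript_id = tid,
                                  exon_number = seq_len(n_ex), stringsAsFactors = FALSE)
      first <- c(ex_start[1], ex_start[1] + utr_len - 1)
      last <- c(ex_end[n_ex] - utr_len + 1, ex_end[n_ex])
      u5 <- if (str == "+") first else last
      u3 <- if (str == "+") last else first
      u5_list[[gi]] <- data.frame(chrom = chrom, start = u5[1], end = u5[2],
                                  strand = str, gene_id = gid, transcript_id = tid,
                                  stringsAsFactors = FALSE)
      u3_list[[gi]] <- data.frame(chrom = chrom, start = u3[1], end = u3[2],
                                  strand = str, gene_id = gid, transcript_id = tid,
                                  stringsAsFactors = FALSE)
    }
  }
  as_gr <- function(lst, extra = character()) {
    df <- do.call(rbind, lst)
    gr <- GenomicRanges::GRanges(df$chrom, IRanges::IRanges(df$start, df$end),
                                 strand = df$strand)
    for (col in c("gene_id", "transcript_id", extra))
      S4Vectors::mcols(gr)[[col]] <- df[[col]]
    gr
  }
  gene_model(as_gr(tx_list), as_gr(ex_list, "exon_number"),
             utr5 = as_gr(u5_list), utr3 = as_gr(u3_list))
}

#' Generate ChIP-seq replicate peak sets with planted targets
#'
#' A reproducible fraction of the target genes receives a peak centered
#' inside the TSS window in at least 2 of `n_reps` replicates; the rest
#' appear in exactly one replicate. Noise peaks are placed outside every
#' TSS window and appear in exactly one replicate.
#'
#' @param model A [gene_model()].
#' @param target_genes Gene ids from the model to receive TSS peaks.
#' @param n_reps Number of replicates (>= 2, default 3).
#' @param reproducible_frac Fraction of target genes with multi-replicate
#'   peaks (default 1).
#' @param n_noise_peaks Number of spurious single-replicate distal peaks.
#' @param peak_width Peak width in bp (default 200).
#' @param tss_window TSS window the peaks must respect (default 3000).
#' @param chrom_len Chromosome length used to place noise peaks.
#' @param seed Integer seed.
#' @return List with `replicates` (list of `GRanges`) and `truth` (data
#'   frame `gene_id`, `reproducible`).
#' @export
gen_chip_replicates <- function(model, target_genes, n_reps = 3,
                                reproducible_frac = 1, n_noise_peaks = 0,
                                peak_width = 200, tss_window = 3000,
                                chrom_len = 1e6, seed = 1) {
  if (n_reps < 2) stop("need >= 2 replicates")
  tss <- model_tss(model)
  known <- S4Vectors::mcols(tss)$gene_id
  if (!all(target_genes %in% known))
    stop("target genes absent from model: ",
         paste(setdiff(target_genes, known), collapse = ", "))
  set.seed(seed)
  nt <- length(target_genes)
  n_rep_genes <- round(reproducible_frac * nt)
  reproducible <- rep(FALSE, nt)
  if (n_rep_genes > 0) reproducible[sample(nt, n_rep_genes)] <- TRUE

  reps <- replicate(n_reps, list(chrom = character(), start = integer()),
                    simplify = FALSE)
  add_peak <- function(r, chrom, start) {
    reps[[r]]$chrom <<- c(reps[[r]]$chrom, chrom)
    reps[[r]]$start <<- c(reps[[r]]$start, start)
  }
  half <- floor(peak_width / 2)
  max_off <- tss_window - half - 50
  for (i in seq_len(nt)) {
    ti <- which(known == target_genes[i])[1]
    pos <- BiocGenerics::start(tss)[ti]
    chrom <- as.character(GenomeInfoDb::seqnames(tss))[ti]
    center <- pos + round(stats::runif(1, -max_off, max_off))
    in_reps <- if (reproducible[i]) sample(n_reps, sample(2:n_reps, 1)) else sample(n_reps, 1)
    for (r in in_reps)
      add_peak(r, chrom, center - half + round(stats::runif(1, -20, 20)))
  }
  if (n_noise_peaks > 0) {
    tss_zones <- GenomicRanges::resize(tss, width = 2 * (tss_window + peak_width) + 1,
                                       fix = "center")
    chroms <- unique(as.character(GenomeInfoDb::seqnames(model$transcripts)))
    placed <- 0L; attempts <- 0L
    while (placed < n_noise_peaks) {
      attempts <- attempts + 1L
      if (attempts > 100 * n_noise_peaks)
        stop("no room for distal noise peaks away from TSS windows")
      chrom <- sample(chroms, 1)
      start <- round(stats::runif(1, 1, chrom_len - peak_width))
      cand <- GenomicRanges::GRanges(chrom, IRanges::IRanges(start, start + peak_width - 1))
      if (GenomicRanges::countOverlaps(cand, tss_zones, ignore.strand = TRUE) > 0) next
      add_peak(sample(n_reps, 1), chrom, start)
      placed <- placed + 1L
    }
  }
  replicates <- lapply(seq_len(n_reps), function(r) {
    d <- reps[[r]]
    if (!length(d$chrom)) return(GenomicRanges::GRanges())
    gr <- GenomicRanges::GRanges(d$chrom,
                                 IRanges::IRanges(d$start, width = peak_width))
    S4Vectors::mcols(gr)$replicate_id <- sprintf("rep%d", r)
    BiocGenerics::sort(gr)
  })
  list(replicates = replicates,
       truth = data.frame(gene_id = target_genes, reproducible = reproducible,
                          stringsAsFactors = FALSE))
}

#' Generate paired knockdown DEG tables with a planted core
#'
#' @param core_genes Genes significant in both tables.
#' @param lineA_only,lineB_only Genes significant in exactly one table.
#' @param null_genes Genes significant in neither.
#' @param fdr_alt Upper bound for significant q-values (default 0.01).
#' @param fdr_null Lower bound for non-significant q-values (default 0.5);
#'   must be >= the downstream threshold.
#' @param seed Integer seed.
#' @return List of two data frames (`line_a`, `line_b`) with `gene_id`,
#'   `log2fc`, `q`.
#' @export
gen_deg_tables <- function(core_genes, lineA_only = character(),
                           lineB_only = character(), null_genes = character(),
                           fdr_alt = 0.01, fdr_null = 0.5, seed = 1) {
  groups <- list(core_genes, lineA_only, lineB_only, null_genes)
  all <- unlist(groups)
  if (anyDuplicated(all)) stop("gene groups must be disjoint")
  if (!(fdr_alt < fdr_null)) stop("need fdr_alt < fdr_null")
  set.seed(seed)
  one_table <- function(sig_genes) {
    sig <- all %in% sig_genes
    data.frame(
      gene_id = all,
      log2fc = ifelse(sig,
                      sample(c(-1, 1), length(all), replace = TRUE) *
                        stats::rnorm(length(all), 2, 0.5),
                      stats::rnorm(length(all), 0, 0.15)),
      q = ifelse(sig, stats::runif(length(all), 0, fdr_alt),
                 stats::runif(length(all), fdr_null, 1)),
      stringsAsFactors = FALSE
    )
  }
  list(line_a = one_table(c(core_genes, lineA_only)),
       line_b = one_table(c(core_genes, lineB_only)))
}

#' Generate NanoString-style raw counts with controls
#'
#' Matched ATC/DTC pairs share a patient id; every gene (controls included)
#' is scaled by a per-sample technical factor; negative controls are drawn
#' from the background-only distribution; positive controls follow a fixed
#' concentration ladder; panel genes get `effect_log2fc` added in ATC
#' samples.
#'
#' @param panel_genes Character vector of endogenous panel genes.
#' @param housekeeping Number of housekeeping genes (default 4).
#' @param n_pos,n_neg Numbers of positive/negative controls (default 6).
#' @param n_pairs Matched patient pairs (>= 2, default 8).
#' @param effect_log2fc Planted ATC - DTC effect on panel genes (log2).
#' @param dispersion Log2-sd of multiplicative noise on endogenous and
#'   housekeeping genes.
#' @param control_dispersion Log2-sd of noise on positive controls.
#' @param scale_sd Log2-sd of the per-sample technical scale factor.
#' @param bg_mean,bg_sd Additive background count distribution.
#' @param seed Integer seed.
#' @return List with `raw` (a [nanostring_raw()]) and `truth` (per-sample
#'   scale factors, planted effect, per-gene base counts).
#' @export
gen_nanostring_counts <- function(panel_genes, housekeeping = 4, n_pos = 6,
                                  n_neg = 6, n_pairs = 8, effect_log2fc = 2,
                                  dispersion = 0.15, control_dispersion = 0.01,
                                  scale_sd = 0.25, bg_mean = 20, bg_sd = 5,
                                  seed = 1) {
  if (n_pairs < 2) stop("need >= 2 pairs")
  set.seed(seed)
  hk_genes <- sprintf("HK%d", seq_len(housekeeping))
  pos_genes <- sprintf("POS_%s", LETTERS[seq_len(n_pos)])
  neg_genes <- sprintf("NEG_%s", LETTERS[seq_len(n_neg)])
  genes <- c(panel_genes, hk_genes, pos_genes, neg_genes)
  cls <- c(rep("Endogenous", length(panel_genes)),
           rep("Housekeeping", housekeeping),
           rep("Positive", n_pos), rep("Negative", n_neg))

  patients <- sprintf("pat%02d", seq_len(n_pairs))
  samples <- data.frame(
    sample_id = as.vector(rbind(paste0(patients, "_ATC"), paste0(patients, "_DTC"))),
    tissue = rep(c("ATC", "DTC"), n_pairs),
    patient_id = rep(patients, each = 2),
    stringsAsFactors = FALSE
  )
  ns <- nrow(samples)
  scale <- 2^stats::rnorm(ns, 0, scale_sd)
  names(scale) <- samples$sample_id

  mu_panel <- 2^stats::runif(length(panel_genes), 8, 11)
  mu_hk <- 2^stats::runif(housekeeping, 9, 11)
  pos_ladder <- 2^seq(15, 10, length.out = n_pos)

  counts <- matrix(0, length(genes), ns, dimnames = list(genes, samples$sample_id))
  bg_draw <- function(n) pmax(stats::rnorm(n, bg_mean, bg_sd), 0)
  for (j in seq_len(ns)) {
    eff <- if (samples$tissue[j] == "ATC") effect_log2fc else 0
    panel <- mu_panel * 2^(eff + stats::rnorm(length(mu_panel), 0, dispersion))
    hk <- mu_hk * 2^stats::rnorm(housekeeping, 0, dispersion)
    pos <- pos_ladder * 2^stats::rnorm(n_pos, 0, control_dispersion)
    signal <- c(panel, hk, pos, rep(0, n_neg)) * scale[j]
    counts[, j] <- round(signal + bg_draw(length(genes)))
  }
  list(
    raw = nanostring_raw(counts, cls, samples),
    truth = list(scale = scale, effect_log2fc = effect_log2fc,
                 mu_panel = stats::setNames(mu_panel, panel_genes))
  )
}
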