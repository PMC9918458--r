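# ChIP-seq / RNA-seq integration: replicate-consensus peak filtering,
# TSS-window target assignment, genomic-feature distribution, DEG-table
# thresholding and the three-way core-program intersection.
#
# Intervals are held as GRanges (1-based closed); rtracklayer performs the
# exact conversions to/from BED-family (0-based half-open) and GTF (1-based
# closed) on disk.

#' Construct a gene model
#'
#' @param transcripts `GRanges` with mcols `gene_id`, `transcript_id`;
#'   strand `+` or `-`. The TSS is the start for `+` transcripts and the
#'   end for `-` transcripts.
#' @param exons `GRanges` with mcols `gene_id`, `transcript_id`,
#'   `exon_number`; every exon must lie within its transcript.
#' @param utr5,utr3 Optional `GRanges` (same mcols minus `exon_number`)
#'   marking untranslated regions.
#' @return A `gene_model` list.
#' @export
gene_model <- function(transcripts, exons,
                       utr5 = GenomicRanges::GRanges(),
                       utr3 = GenomicRanges::GRanges()) {
  stopifnot(methods::is(transcripts, "GRanges"), methods::is(exons, "GRanges"))
  if (!all(c("gene_id", "transcript_id") %in% names(S4Vectors::mcols(transcripts))))
    stop("transcripts need gene_id and transcript_id")
  if (any(!as.character(BiocGenerics::strand(transcripts)) %in% c("+", "-")))
    stop("transcript strand must be + or -")
  tx_of <- S4Vectors::mcols(exons)$transcript_id
  hit <- match(tx_of, S4Vectors::mcols(transcripts)$transcript_id)
  if (anyNA(hit)) stop("exon references unknown transcript")
  inside <- BiocGenerics::start(exons) >= BiocGenerics::start(transcripts)[hit] &
    BiocGenerics::end(exons) <= BiocGenerics::end(transcripts)[hit]
  if (!all(inside)) stop("exon outside its transcript")
  structure(list(transcripts = transcripts, exons = exons, utr5 = utr5, utr3 = utr3),
            class = "gene_model")
}

# TSS positions of all transcripts as a width-1 GRanges
model_tss <- function(model) {
  tx <- model$transcripts
  pos <- ifelse(as.character(BiocGenerics::strand(tx)) == "+",
                BiocGenerics::start(tx), BiocGenerics::end(tx))
  GenomicRanges::GRanges(
    GenomeInfoDb::seqnames(tx),
    IRanges::IRanges(pos, width = 1),
    strand = BiocGenerics::strand(tx),
    gene_id = S4Vectors::mcols(tx)$gene_id,
    transcript_id = S4Vectors::mcols(tx)$transcript_id
  )
}

#' Write a gene model to GTF
#'
#' Emits transcript, exon and UTR records; coordinates follow the GTF
#' 1-based closed convention.
#'
#' @param model A [gene_model()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_gene_model_gtf <- function(model, path) {
  pieces <- list(
    transcript = model$transcripts,
    exon = model$exons,
    five_prime_utr = model$utr5,
    three_prime_utr = model$utr3
  )
  grl <- lapply(names(pieces), function(ty) {
    gr <- pieces[[ty]]
    if (!length(gr)) return(NULL)
    S4Vectors::mcols(gr)$type <- ty
    S4Vectors::mcols(gr)$source <- "trendsig"
    gr
  })
  all <- do.call(c, Filter(Negate(is.null), unname(grl)))
  all <- GenomicRanges::sort(all, ignore.strand = TRUE)
  rtracklayer::export(all, path, format = "gtf")
  invisible(path)
}

#' Read a gene model from GTF
#'
#' @param path GTF file with `transcript` and `exon` records carrying
#'   `gene_id`/`transcript_id` attributes; `five_prime_utr` and
#'   `three_prime_utr` records are honoured when present.
#' @return A [gene_model()].
#' @export
read_gene_model_gtf <- function(path) {
  gr <- rtracklayer::import(path, format = "gtf")
  ty <- S4Vectors::mcols(gr)$type
  pick <- function(t, cols) {
    out <- gr[ty == t]
    S4Vectors::mcols(out) <- S4Vectors::mcols(out)[, cols, drop = FALSE]
    GenomicRanges::sort(out, ignore.strand = TRUE)
  }
  tx <- pick("transcript", c("gene_id", "transcript_id"))
  ex <- pick("exon", c("gene_id", "transcript_id", "exon_number"))
  S4Vectors::mcols(ex)$exon_number <- as.integer(S4Vectors::mcols(ex)$exon_number)
  gene_model(tx, ex,
             utr5 = pick("five_prime_utr", c("gene_id", "transcript_id")),
             utr3 = pick("three_prime_utr", c("gene_id", "transcript_id")))
}

#' Read a peak file (BED6 or narrowPeak)
#'
#' Column count is auto-detected: 10 tab-separated columns are read as
#' ENCODE narrowPeak (summit offset kept), otherwise the file is read as
#' BED.
#'
#' @param path Peak file path.
#' @param replicate_id Optional replicate label stored on the ranges.
#' @return `GRanges`; narrowPeak input carries a `peak` (summit offset)
#'   column.
#' @export
read_peaks <- function(path, replicate_id = NULL) {
  first <- strsplit(readLines(path, n = 1), "\t", fixed = TRUE)[[1]]
  if (length(first) == 10L) {
    gr <- rtracklayer::import(path, format = "BED",
      extraCols = c(signalValue = "numeric", pValue = "numeric",
                    qValue = "numeric", peak = "integer"))
  } else {
    gr <- rtracklayer::import(path, format = "BED")
  }
  if (!is.null(replicate_id)) S4Vectors::mcols(gr)$replicate_id <- replicate_id
  gr
}

#' Write peaks as BED6
#'
#' @param peaks `GRanges`.
#' @param path Output path (0-based half-open BED on disk).
#' @return `path`, invisibly.
#' @export
write_peaks_bed <- function(peaks, path) {
  if (is.null(S4Vectors::mcols(peaks)$name))
    S4Vectors::mcols(peaks)$name <- sprintf("peak_%d", seq_along(peaks))
  if (is.null(S4Vectors::mcols(peaks)$score)) S4Vectors::mcols(peaks)$score <- 0L
  rtracklayer::export(peaks, path, format = "bed")
  invisible(path)
}

#' Replicate-consensus peak filtering
#'
#' Merges significant peaks from all replicates (union of overlapping
#' intervals) and retains a merged span iff, somewhere inside it, peaks from
#' at least `min_support` distinct replicates overlap the same base.
#' Retained intervals are the full merged spans, sorted and disjoint.
#'
#' @param replicates List of `GRanges`, one per replicate.
#' @param min_support Minimum number of distinct supporting replicates
#'   (default 2, the "at least 2 of 3" rule).
#' @return `GRanges` of consensus peaks with an `n_replicates` column
#'   (maximum distinct-replicate co-coverage within the span).
#' @export
consensus_peaks <- function(replicates, min_support = 2) {
  if (min_support > length(replicates))
    stop("min_support exceeds the number of replicates")
  if (min_support < 1) stop("min_support must be >= 1")
  flat <- lapply(replicates, function(gr) {
    gr <- GenomicRanges::reduce(gr, min.gapwidth = 0L)
    S4Vectors::mcols(gr) <- NULL
    gr
  })
  all_peaks <- do.call(c, flat)
  merged <- GenomicRanges::reduce(all_peaks, min.gapwidth = 0L)
  if (!length(merged)) return(merged)
  # distinct-replicate coverage on a shared chromosome namespace
  chrs <- GenomeInfoDb::seqlevels(all_peaks)
  widths <- stats::setNames(rep(max(BiocGenerics::end(all_peaks)) + 1L, length(chrs)), chrs)
  cov <- Reduce(`+`, lapply(flat, function(gr) {
    GenomeInfoDb::seqlevels(gr) <- chrs
    GenomicRanges::coverage(gr, width = widths)
  }))
  supported <- GenomicRanges::GRanges(
    IRanges::slice(cov, lower = min_support, rangesOnly = TRUE))
  keep <- GenomicRanges::countOverlaps(merged, supported) > 0
  out <- merged[keep]
  # deepest distinct-replicate co-coverage within each retained span
  out_chr <- as.character(GenomeInfoDb::seqnames(out))
  S4Vectors::mcols(out)$n_replicates <- vapply(seq_along(out), function(i) {
    as.integer(max(S4Vectors::window(cov[[out_chr[i]]],
                                     BiocGenerics::start(out)[i],
                                     BiocGenerics::end(out)[i])))
  }, integer(1))
  BiocGenerics::sort(out)
}

# peak anchor position: summit when a narrowPeak offset is present, else midpoint
peak_anchor <- function(peaks) {
  mc <- S4Vectors::mcols(peaks)
  anchor <- floor((BiocGenerics::start(peaks) + BiocGenerics::end(peaks)) / 2)
  if (!is.null(mc$peak)) {
    has <- !is.na(mc$peak) & mc$peak >= 0
    anchor[has] <- BiocGenerics::start(peaks)[has] + mc$peak[has]
  }
  anchor
}

#' Assign peaks to genes by nearest TSS with a window rule
#'
#' Each peak is anchored at its summit (narrowPeak) or midpoint and matched
#' to the nearest transcript TSS (smallest absolute distance; ties go to the
#' smaller strand-aware signed distance, then the lexicographically smaller
#' gene id). A gene is a target iff some peak anchor lies within
#' `tss_window` bp of one of its TSSs. Peaks on chromosomes absent from the
#' model are annotated `unplaced` and never contribute targets.
#'
#' @param peaks `GRanges` of peaks.
#' @param model A [gene_model()].
#' @param tss_window Window half-width in bp (default 3000, i.e. +/- 3 kb).
#' @return List with `annotation` (data frame: peak coordinates, anchor,
#'   `gene_id`, `transcript_id`, signed `distance` where negative is
#'   upstream, logical `is_target`) and `targets` (sorted gene ids).
#' @export
assign_peaks_to_genes <- function(peaks, model, tss_window = 3000) {
  tss <- model_tss(model)
  anchor <- peak_anchor(peaks)
  chr <- as.character(GenomeInfoDb::seqnames(peaks))
  tss_chr <- as.character(GenomeInfoDb::seqnames(tss))
  n <- length(peaks)
  gene <- tx <- rep(NA_character_, n)
  dist <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    cand <- which(tss_chr == chr[i])
    if (!length(cand)) next
    pos <- BiocGenerics::start(tss)[cand]
    signed <- anchor[i] - pos
    minus <- as.character(BiocGenerics::strand(tss))[cand] == "-"
    signed[minus] <- -signed[minus]
    ord <- order(abs(signed), signed,
                 S4Vectors::mcols(tss)$gene_id[cand])
    best <- cand[ord[1]]
    gene[i] <- S4Vectors::mcols(tss)$gene_id[best]
    tx[i] <- S4Vectors::mcols(tss)$transcript_id[best]
    dist[i] <- signed[ord[1]]
  }
  is_target <- !is.na(dist) & abs(dist) <= tss_window
  ann <- data.frame(
    chrom = chr,
    start = BiocGenerics::start(peaks),
    end = BiocGenerics::end(peaks),
    anchor = anchor,
    gene_id = ifelse(is.na(gene), "unplaced", gene),
    transcript_id = tx,
    distance = dist,
    is_target = is_target,
    stringsAsFactors = FALSE
  )
  list(annotation = ann,
       targets = sort(unique(gene[is_target])))
}

#' Genomic distribution of peaks over feature categories
#'
#' Each peak anchor is assigned exactly one category with precedence
#' TSS > 5'UTR > 3'UTR > exon > intron > downstream > distal_intergenic.
#' "TSS" means within `tss_window` bp of any TSS; "downstream" means within
#' `downstream_window` bp past a transcript end (strand-aware).
#'
#' @param peaks `GRanges`.
#' @param model A [gene_model()].
#' @param tss_window TSS window half-width (default 3000).
#' @param downstream_window Window past the transcript end (default 3000).
#' @return Data frame with `category`, `count`, `fraction` (fractions sum
#'   to 1) over the seven categories, in precedence order.
#' @export
genomic_distribution <- function(peaks, model, tss_window = 3000,
                                 downstream_window = 3000) {
  cats <- c("TSS", "5'UTR", "3'UTR", "exon", "intron", "downstream",
            "distal_intergenic")
  anchor_gr <- GenomicRanges::GRanges(
    GenomeInfoDb::seqnames(peaks),
    IRanges::IRanges(peak_anchor(peaks), width = 1))
  tss <- model_tss(model)
  tss_win <- GenomicRanges::resize(tss, width = 2 * tss_window + 1, fix = "center")
  tx <- model$transcripts
  tes_pos <- ifelse(as.character(BiocGenerics::strand(tx)) == "+",
                    BiocGenerics::end(tx), BiocGenerics::start(tx))
  plus <- as.character(BiocGenerics::strand(tx)) == "+"
  down <- GenomicRanges::GRanges(
    GenomeInfoDb::seqnames(tx),
    IRanges::IRanges(
      start = ifelse(plus, tes_pos + 1, pmax(tes_pos - downstream_window, 1)),
      end = ifelse(plus, tes_pos + downstream_window, pmax(tes_pos - 1, 1))))
  in_any <- function(subject) {
    if (!length(subject)) return(rep(FALSE, length(anchor_gr)))
    GenomicRanges::countOverlaps(anchor_gr, subject, ignore.strand = TRUE) > 0
  }
  hit <- cbind(
    TSS = in_any(tss_win),
    `5'UTR` = in_any(model$utr5),
    `3'UTR` = in_any(model$utr3),
    exon = in_any(model$exons),
    intron = in_any(tx) ,
    downstream = in_any(down),
    distal_intergenic = TRUE
  )
  # intron = inside a transcript body but not in an exon; precedence handles TSS/UTR
  assigned <- apply(hit, 1, function(h) cats[which(h)[1]])
  counts <- table(factor(assigned, levels = cats))
  n <- length(anchor_gr)
  data.frame(
    category = cats,
    count = as.integer(counts),
    fraction = if (n) as.numeric(counts) / n else rep(0, length(cats)),
    stringsAsFactors = FALSE
  )
}

#' Threshold a differential-expression table
#'
#' @param table Data frame with `gene_id` and `q` (FDR-adjusted p) columns;
#'   q-values must lie in `[0, 1]`.
#' @param fdr Strict cutoff (default 0.05): genes with `q < fdr` are kept.
#' @return Sorted character vector of significant gene ids (duplicates
#'   collapsed keeping the minimum q).
#' @export
threshold_deg <- function(table, fdr = 0.05) {
  if (!all(c("gene_id", "q") %in% names(table)))
    stop("DEG table needs gene_id and q columns")
  bad <- which(is.na(table$q) | table$q < 0 | table$q > 1)
  if (length(bad)) stop("malformed q-value at row ", bad[1])
  sig <- table[table$q < fdr, , drop = FALSE]
  sort(unique(sig$gene_id))
}

#' Three-way core-program intersection
#'
#' Intersects the DEG sets of two knockdown cell lines with the ChIP-derived
#' direct-target list and reports all seven exclusive Venn regions.
#'
#' @param deg_a,deg_b Character vectors of significant genes per cell line.
#' @param chip_targets Character vector of ChIP target genes.
#' @return List with `core` (sorted triple intersection), `sets` (the three
#'   deduplicated input sets) and `venn` (named counts of the 7 exclusive
#'   regions: `a_only`, `b_only`, `chip_only`, `ab`, `a_chip`, `b_chip`,
#'   `core`; they sum to the union size).
#' @export
core_program <- function(deg_a, deg_b, chip_targets) {
  a <- unique(deg_a); b <- unique(deg_b); c_ <- unique(chip_targets)
  core <- sort(intersect(intersect(a, b), c_))
  venn <- c(
    a_only = length(setdiff(setdiff(a, b), c_)),
    b_only = length(setdiff(setdiff(b, a), c_)),
    chip_only = length(setdiff(setdiff(c_, a), b)),
    ab = length(setdiff(intersect(a, b), c_)),
    a_chip = length(setdiff(intersect(a, c_), b)),
    b_chip = length(setdiff(intersect(b, c_), a)),
    core = length(core)
  )
  list(core = core,
       sets = list(deg_a = sort(a), deg_b = sort(b), chip_targets = sort(c_)),
       venn = venn)
}
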