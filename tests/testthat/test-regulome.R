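suppressPackageStartupMessages({
  library(GenomicRanges)
})

gr1 <- function(start, end, chrom = "chr1")
  GRanges(chrom, IRanges(start, end))

test_that("consensus peaks implement merge-then-support-filter", {
  # A [100,200), B [150,250), C [400,500) in 0-based terms
  cons <- consensus_peaks(list(gr1(101, 200), gr1(151, 250), gr1(401, 500)),
                          min_support = 2)
  expect_equal(length(cons), 1L)
  expect_equal(start(cons), 101)
  expect_equal(end(cons), 250)
  expect_equal(mcols(cons)$n_replicates, 2L)

  # identical peak in all replicates is retained unchanged
  same <- gr1(1000, 1200)
  cons2 <- consensus_peaks(list(same, same, same))
  expect_equal(start(cons2), 1000)
  expect_equal(end(cons2), 1200)
  expect_equal(mcols(cons2)$n_replicates, 3L)

  expect_error(consensus_peaks(list(same, same), min_support = 3), "exceeds")
  expect_equal(length(consensus_peaks(list(gr1(1, 10), gr1(100, 110),
                                           gr1(200, 210)))), 0L)
})

test_that("consensus peaks equal the per-base coverage oracle on random sets", {
  chrom_len <- 100000
  for (seed in 1:5) {
    set.seed(seed)
    reps <- lapply(1:3, function(r) {
      n <- sample(8:15, 1)
      s <- sort(sample(chrom_len - 500, n))
      gr1(s, s + sample(100:400, n, replace = TRUE))
    })
    for (k in 2:3) {
      cons <- consensus_peaks(reps, min_support = k)
      oracle <- consensus_oracle(lapply(reps, function(g)
        data.frame(start = start(g), end = end(g))), chrom_len, min_support = k)
      expect_equal(start(cons), oracle$start)
      expect_equal(end(cons), oracle$end)
    }
    # monotone: raising support never enlarges the set
    expect_lte(length(consensus_peaks(reps, 3)), length(consensus_peaks(reps, 2)))
    # retained intervals are disjoint and sorted
    cons <- consensus_peaks(reps, 2)
    if (length(cons) > 1) {
      expect_true(all(start(cons)[-1] > end(cons)[-length(cons)]))
    }
  }
})

test_that("TSS-window target assignment honours the strand convention", {
  tx <- GRanges(c("chr1", "chr1"), IRanges(c(10000, 50000), c(20000, 60000)),
                strand = c("+", "-"),
                gene_id = c("gPLUS", "gMINUS"),
                transcript_id = c("gPLUS_t1", "gMINUS_t1"))
  ex <- GRanges(c("chr1", "chr1", "chr1", "chr1"),
                IRanges(c(10000, 15000, 50000, 55000),
                        c(12000, 20000, 52000, 60000)),
                strand = c("+", "+", "-", "-"),
                gene_id = c("gPLUS", "gPLUS", "gMINUS", "gMINUS"),
                transcript_id = c("gPLUS_t1", "gPLUS_t1", "gMINUS_t1", "gMINUS_t1"),
                exon_number = c(1L, 2L, 1L, 2L))
  model <- gene_model(tx, ex)
  # '+' TSS = start: peak [7000,7200) has midpoint 7100, distance -2900 -> target
  peaks <- suppressWarnings(
    c(gr1(7001, 7200), gr1(13001, 13200), gr1(62901, 63100),
      GRanges("chrX", IRanges(100, 200))))
  ann <- assign_peaks_to_genes(peaks, model, tss_window = 3000)
  expect_equal(ann$annotation$gene_id[1], "gPLUS")
  expect_equal(ann$annotation$distance[1], -2900)
  expect_true(ann$annotation$is_target[1])
  # midpoint 3100 past the TSS: nearest gene recorded, not a target
  expect_equal(ann$annotation$gene_id[2], "gPLUS")
  expect_equal(ann$annotation$distance[2], 3100)
  expect_false(ann$annotation$is_target[2])
  # '-' TSS = end: peak upstream (to the right) of gMINUS TSS at 60000
  expect_equal(ann$annotation$gene_id[3], "gMINUS")
  expect_equal(ann$annotation$distance[3], -3000)
  expect_true(ann$annotation$is_target[3])
  # unplaced chromosome
  expect_equal(ann$annotation$gene_id[4], "unplaced")
  expect_setequal(ann$targets, c("gPLUS", "gMINUS"))
  # target set is monotone in the window size
  small <- assign_peaks_to_genes(peaks, model, tss_window = 1000)
  expect_true(all(small$targets %in% ann$targets))
})

test_that("peak annotation matches the exhaustive per-peak oracle", {
  model <- gen_gene_model(12, n_chroms = 2, chrom_len = 5e5, seed = 9)
  set.seed(99)
  n <- 40
  peaks <- GRanges(sample(c("chr1", "chr2"), n, replace = TRUE),
                   IRanges(sample(5e5 - 400, n), width = 300))
  ann <- assign_peaks_to_genes(peaks, model, tss_window = 3000)
  tx <- model$transcripts
  tss_df <- data.frame(
    chrom = as.character(seqnames(tx)),
    pos = ifelse(as.character(strand(tx)) == "+", start(tx), end(tx)),
    strand = as.character(strand(tx)),
    gene_id = mcols(tx)$gene_id, stringsAsFactors = FALSE)
  anchors <- floor((start(peaks) + end(peaks)) / 2)
  oracle <- annotate_oracle(anchors, as.character(seqnames(peaks)), tss_df)
  expect_equal(ann$annotation$gene_id,
               ifelse(is.na(oracle$gene), "unplaced", oracle$gene))
  expect_equal(ann$annotation$distance, oracle$distance)
  expect_setequal(ann$targets, unique(oracle$gene[oracle$is_target]))
})

test_that("genomic distribution respects category precedence and sums to one", {
  model <- gen_gene_model(10, n_chroms = 2, chrom_len = 5e5, seed = 5)
  tx <- model$transcripts
  # a peak in the TSS window that also overlaps the first exon -> TSS wins
  tss_pos <- ifelse(as.character(strand(tx)) == "+", start(tx), end(tx))
  inside <- GRanges(seqnames(tx)[1], IRanges(tss_pos[1] - 50, tss_pos[1] + 250))
  dist <- genomic_distribution(inside, model)
  expect_equal(dist$count[dist$category == "TSS"], 1)
  # a far-away midpoint -> distal intergenic
  far <- GRanges("chr1", IRanges(499000, 499200))
  dist2 <- genomic_distribution(far, model)
  expect_equal(dist2$count[dist2$category == "distal_intergenic"], 1)

  set.seed(41)
  n <- 60
  peaks <- GRanges(sample(c("chr1", "chr2"), n, replace = TRUE),
                   IRanges(sample(5e5 - 400, n), width = 200))
  dist3 <- genomic_distribution(peaks, model)
  expect_equal(sum(dist3$fraction), 1, tolerance = 1e-9)
  expect_equal(sum(dist3$count), n)
  # independent per-peak classification oracle
  anchors <- floor((start(peaks) + end(peaks)) / 2)
  chroms <- as.character(seqnames(peaks))
  in_iv <- function(a, ch, gr) {
    idx <- as.character(seqnames(gr)) == ch
    any(a >= start(gr)[idx] & a <= end(gr)[idx])
  }
  tss_win <- GRanges(seqnames(tx), IRanges(tss_pos - 3000, tss_pos + 3000))
  plus <- as.character(strand(tx)) == "+"
  tes_pos <- ifelse(plus, end(tx), start(tx))
  down <- GRanges(seqnames(tx),
                  IRanges(ifelse(plus, tes_pos + 1, pmax(tes_pos - 3000, 1)),
                          ifelse(plus, tes_pos + 3000, pmax(tes_pos - 1, 1))))
  want <- vapply(seq_len(n), function(i) {
    a <- anchors[i]; ch <- chroms[i]
    if (in_iv(a, ch, tss_win)) "TSS"
    else if (in_iv(a, ch, model$utr5)) "5'UTR"
    else if (in_iv(a, ch, model$utr3)) "3'UTR"
    else if (in_iv(a, ch, model$exons)) "exon"
    else if (in_iv(a, ch, tx)) "intron"
    else if (in_iv(a, ch, down)) "downstream"
    else "distal_intergenic"
  }, character(1))
  expect_equal(dist3$count, as.integer(table(factor(want, levels = dist3$category))))
})

test_that("DEG thresholding is strict and collapses duplicates", {
  tab <- data.frame(gene_id = c("a", "b", "c", "a"),
                    q = c(0.01, 0.05, 0.049, 0.2), stringsAsFactors = FALSE)
  expect_equal(threshold_deg(tab, fdr = 0.05), c("a", "c"))
  expect_length(threshold_deg(tab[0, ], 0.05), 0)
  tab$q[2] <- 1.5
  expect_error(threshold_deg(tab), "malformed q-value at row 2")
})

test_that("core program reports the triple intersection and all Venn regions", {
  cp <- core_program(c("A", "B", "C"), c("B", "C", "D"), c("C", "B", "E"))
  expect_equal(cp$core, c("B", "C"))
  expect_equal(unname(cp$venn["core"]), 2)
  expect_equal(sum(cp$venn), length(unique(c("A", "B", "C", "D", "E"))))
  expect_length(core_program(character(), c("B"), c("B"))$core, 0)
  expect_true(all(cp$core %in% c("A", "B", "C")))
})

test_that("peak files round-trip through BED and narrowPeak", {
  tmp_bed <- tempfile(fileext = ".bed")
  peaks <- gr1(c(101, 501), c(200, 700))
  write_peaks_bed(peaks, tmp_bed)
  # BED on disk is 0-based half-open
  raw <- read.table(tmp_bed, sep = "\t")
  expect_equal(raw$V2, c(100, 500))
  expect_equal(raw$V3, c(200, 700))
  back <- read_peaks(tmp_bed, replicate_id = "rep1")
  expect_equal(start(back), start(peaks))
  expect_equal(end(back), end(peaks))
  expect_equal(unique(mcols(back)$replicate_id), "rep1")

  # narrowPeak with summit offsets
  tmp_np <- tempfile(fileext = ".narrowPeak")
  writeLines(c("chr1\t100\t200\tpk1\t0\t.\t5.5\t3.2\t2.1\t50",
               "chr1\t500\t700\tpk2\t0\t.\t6.5\t4.2\t3.1\t-1"), tmp_np)
  np <- read_peaks(tmp_np)
  expect_equal(mcols(np)$peak, c(50L, -1L))
  # summit used as anchor when >= 0, midpoint otherwise
  model <- gen_gene_model(2, n_chroms = 1, chrom_len = 1e5, seed = 1)
  ann <- assign_peaks_to_genes(np, model)
  expect_equal(ann$annotation$anchor, c(101 + 50, floor((501 + 700) / 2)))
})
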