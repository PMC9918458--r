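suppressPackageStartupMessages(library(GenomicRanges))

test_that("zero-noise expression reproduces planted group means exactly", {
  planted <- data.frame(gene = 1, direction = "up", archetype = "S3",
                        effect_step1 = 1, effect_step2 = 1,
                        stringsAsFactors = FALSE)
  cfg <- synth_expression_config(
    n_norm = 4, n_dtc = 4, n_atc = 4, n_studies = 1, n_genes = 5,
    planted = planted, within_sd = 0, batch_sd = 0,
    probe_multiplicity = c(`1` = 1, `2` = 0, `3` = 0), seed = 3)
  sim <- gen_multistudy_expression(cfg)
  probe <- sim$probe_map$probe_id[sim$probe_map$gene_id == sim$truth$gene_id[1]]
  tis <- sim$sheet$tissue
  means <- tapply(sim$matrix[probe, ], tis, mean)
  b <- means[["NORM"]]
  expect_equal(means[["DTC"]], b + 1)
  expect_equal(means[["ATC"]], b + 2)
  # S1 archetype: full step-1 effect, nothing extra at ATC
  cfg$planted$archetype <- "S1"
  sim1 <- gen_multistudy_expression(cfg)
  m1 <- tapply(sim1$matrix[probe, ], tis, mean)
  expect_equal(m1[["DTC"]] - m1[["NORM"]], 1)
  expect_equal(m1[["ATC"]], m1[["DTC"]])
  # S2: nothing at DTC, full step-2 effect at ATC
  cfg$planted$archetype <- "S2"
  sim2 <- gen_multistudy_expression(cfg)
  m2 <- tapply(sim2$matrix[probe, ], tis, mean)
  expect_equal(m2[["DTC"]], m2[["NORM"]])
  expect_equal(m2[["ATC"]] - m2[["DTC"]], 1)
  # down direction mirrors
  cfg$planted$direction <- "down"
  simd <- gen_multistudy_expression(cfg)
  md <- tapply(simd$matrix[probe, ], tis, mean)
  expect_equal(md[["ATC"]] - md[["DTC"]], -1)
})

test_that("expression generation is deterministic under the seed", {
  cfg <- synth_expression_config(n_norm = 6, n_dtc = 6, n_atc = 5,
                                 n_studies = 2, n_genes = 50,
                                 planted = default_planted(2), seed = 10)
  a <- gen_multistudy_expression(cfg)
  b <- gen_multistudy_expression(cfg)
  expect_identical(a$matrix, b$matrix)
  expect_identical(a$truth, b$truth)
  cfg2 <- cfg; cfg2$seed <- 11
  c <- gen_multistudy_expression(cfg2)
  expect_false(identical(a$matrix, c$matrix))
  # no planted genes -> empty truth, class means equal up to noise
  cfg3 <- synth_expression_config(n_norm = 4, n_dtc = 4, n_atc = 4,
                                  n_studies = 1, n_genes = 10, planted = NULL,
                                  within_sd = 0, batch_sd = 0, seed = 1)
  sim3 <- gen_multistudy_expression(cfg3)
  expect_equal(nrow(sim3$truth), 0)
  expect_equal(length(unique(as.vector(sim3$matrix[1, ]))), 1L)
  # invalid planted index is rejected
  expect_error(synth_expression_config(
    n_genes = 5, planted = data.frame(gene = 9, direction = "up",
                                      archetype = "S1", effect_step1 = 1,
                                      effect_step2 = 0)), "outside")
})

test_that("interaction network generator hits its edge probabilities exactly at 0/1", {
  full <- gen_interaction_network(c("A", "B", "C"), c("X", "Y"),
                                  p_within = 1, p_background = 0, seed = 1)
  key <- paste(pmin(full$gene_a, full$gene_b), pmax(full$gene_a, full$gene_b))
  expect_setequal(key, c("A B", "A C", "B C"))
  empty <- gen_interaction_network(c("A", "B"), c("X"), 0, 0, seed = 1)
  expect_equal(nrow(empty), 0)
  # reproducible under seed
  g1 <- gen_interaction_network(sprintf("m%d", 1:20), sprintf("b%d", 1:30),
                                p_within = 0.8, p_background = 0.05, seed = 42)
  g2 <- gen_interaction_network(sprintf("m%d", 1:20), sprintf("b%d", 1:30),
                                p_within = 0.8, p_background = 0.05, seed = 42)
  expect_identical(g1, g2)
  expect_error(gen_interaction_network(c("A"), c("A", "B")), "disjoint")
})

test_that("gene models satisfy the strand/TSS conventions and pack feasibly", {
  gm <- gen_gene_model(8, n_chroms = 2, chrom_len = 5e5, seed = 2, strand = "+")
  expect_true(all(as.character(strand(gm$transcripts)) == "+"))
  gm2 <- gen_gene_model(2, n_chroms = 1, chrom_len = 1e5, seed = 4)
  tx <- gm2$transcripts
  expect_equal(length(tx), 2L)
  # transcripts disjoint
  expect_equal(length(GenomicRanges::reduce(tx, ignore.strand = TRUE)), 2L)
  # every transcript has >= 2 exons
  expect_true(all(table(mcols(gm2$exons)$transcript_id) >= 2))
  expect_error(gen_gene_model(1000, n_chroms = 1, chrom_len = 1e5),
               "infeasible packing")
  # GTF round trip preserves the model
  tmp <- tempfile(fileext = ".gtf")
  write_gene_model_gtf(gm2, tmp)
  back <- read_gene_model_gtf(tmp)
  for (part in c("transcripts", "exons", "utr5", "utr3")) {
    a <- gm2[[part]]; b <- back[[part]]
    expect_equal(start(a), start(b))
    expect_equal(end(a), end(b))
    expect_equal(as.character(strand(a)), as.character(strand(b)))
    expect_equal(mcols(a)$gene_id, mcols(b)$gene_id)
  }
})

test_that("ChIP replicate generator plants consensus-recoverable targets", {
  model <- gen_gene_model(10, n_chroms = 2, chrom_len = 5e5, seed = 6)
  genes <- sprintf("gene%03d", 1:10)
  # fully reproducible, no noise: consensus recovers exactly the target list
  chip <- gen_chip_replicates(model, genes, reproducible_frac = 1,
                              n_noise_peaks = 0, seed = 7)
  cons <- consensus_peaks(chip$replicates)
  ann <- assign_peaks_to_genes(cons, model)
  expect_setequal(ann$targets, genes)
  # nothing reproducible: consensus is empty
  chip0 <- gen_chip_replicates(model, genes, reproducible_frac = 0,
                               n_noise_peaks = 5, seed = 8)
  expect_equal(length(consensus_peaks(chip0$replicates)), 0L)
  # mixed: consensus targets = reproducible planted targets
  chipm <- gen_chip_replicates(model, genes, reproducible_frac = 0.6,
                               n_noise_peaks = 10, seed = 9)
  consm <- consensus_peaks(chipm$replicates)
  annm <- assign_peaks_to_genes(consm, model)
  expect_setequal(annm$targets,
                  chipm$truth$gene_id[chipm$truth$reproducible])
  expect_error(gen_chip_replicates(model, c("nope")), "absent")
})

test_that("DEG-table generator plants a recoverable core", {
  core <- sprintf("core%02d", 1:50)
  degs <- gen_deg_tables(core, lineA_only = sprintf("a%02d", 1:10),
                         lineB_only = sprintf("b%02d", 1:10),
                         null_genes = sprintf("n%02d", 1:30), seed = 5)
  sa <- threshold_deg(degs$line_a, 0.05)
  sb <- threshold_deg(degs$line_b, 0.05)
  cp <- core_program(sa, sb, c(core, sprintf("extra%d", 1:5)))
  expect_equal(cp$core, sort(core))
  expect_equal(unname(cp$venn["core"]), 50)
  # empty core
  degs0 <- gen_deg_tables(character(), lineA_only = "a1", seed = 1)
  expect_length(core_program(threshold_deg(degs0$line_a),
                             threshold_deg(degs0$line_b), "a1")$core, 0)
  expect_error(gen_deg_tables(c("x"), lineA_only = "x"), "disjoint")
})

test_that("truth tables stay consistent with files written to disk", {
  dir <- tempfile("bundle")
  cfg <- synth_expression_config(n_norm = 8, n_dtc = 8, n_atc = 6,
                                 n_studies = 2, n_genes = 80,
                                 planted = default_planted(3), seed = 12)
  paths <- write_synthetic_bundle(dir, cfg, n_background = 30)
  m <- read_expression_tsv(paths$expression)
  sheet <- read_sample_sheet(paths$sheet)
  pm <- read_probe_map(paths$probe_map)
  sim <- gen_multistudy_expression(cfg)
  expect_equal(m, sim$matrix, tolerance = 1e-9)
  expect_equal(sheet, sim$sheet)
  expect_equal(pm, sim$probe_map)
  truth <- jsonlite::read_json(paths$truth, simplifyVector = TRUE)
  expect_setequal(truth$gene_id, sim$truth$gene_id)
  edges <- read_edge_list(paths$edges)
  expect_true(all(c(edges$gene_a, edges$gene_b) %in% pm$gene_id))
})
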