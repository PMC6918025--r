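test_that("simulated pools honor construction guarantees and determinism", {
  cfg <- sim_config(n_genes = 10, barcodes_per_gene_mean = 3,
                    intergenic_fraction = 0.2, seed = 7)
  sim <- simulate_pool(cfg)
  map <- pool_gene_map(sim$pool)
  expect_true(all(sim$genes$gene_id %in% map$gene_id))  # every gene covered
  expect_false(anyDuplicated(sim$pool$barcode) > 0)
  expect_true(all(nchar(sim$pool$barcode) == 20))
  expect_equal(sum(sim$truth$abundance), 1)

  # same seed -> identical; different seed -> different barcodes
  sim2 <- simulate_pool(cfg)
  expect_identical(sim$pool, sim2$pool)
  expect_identical(sim$truth, sim2$truth)
  sim3 <- simulate_pool(sim_config(n_genes = 10, barcodes_per_gene_mean = 3,
                                   intergenic_fraction = 0.2, seed = 8))
  expect_false(identical(sort(sim3$pool$barcode), sort(sim$pool$barcode)))

  # no intergenic barcodes: everything assigned to exactly one gene
  sim0 <- simulate_pool(sim_config(n_genes = 10, intergenic_fraction = 0,
                                   seed = 7))
  expect_true(all(sim0$pool$assigned_genes != ""))
  expect_true(all(lengths(strsplit(sim0$pool$assigned_genes, ";")) == 1))
})

test_that("BarSeq counts conserve depth and realize the selection model", {
  cfg <- sim_config(n_genes = 40, depth_per_sample = 1e5,
                    fitness_effects = list(gene_0001 = c(dgalua = -0.5)),
                    seed = 3)
  sim <- simulate_pool(cfg)
  bs <- simulate_barseq_counts(sim$pool, sim$truth, "dgalua", cfg)
  expect_true(all(colSums(bs$t0) == cfg$depth_per_sample))
  expect_true(all(colSums(bs$counts) == cfg$depth_per_sample))
  expect_error(simulate_barseq_counts(sim$pool, sim$truth, "xylose", cfg),
               "unknown condition")

  # planted gene: expected raw log2 ratio ~ g * f = -3 vs the neutral pool
  gf <- score_gene_fitness(bs$t0, bs$counts, sim$pool, "dgalua")
  planted <- gf$fitness[gf$gene_id == "gene_0001"]
  expect_lt(planted, -2)
  expect_gt(planted, -4)
  expect_lt(abs(mean(gf$fitness[gf$gene_id != "gene_0001"])), 0.15)
})

test_that("neutral pool strain scores shrink with depth", {
  cfg_lo <- sim_config(n_genes = 50, depth_per_sample = 2e4, seed = 5)
  cfg_hi <- sim_config(n_genes = 50, depth_per_sample = 2e6, seed = 5)
  sim <- simulate_pool(cfg_lo)
  st_lo <- simulate_barseq_counts(sim$pool, sim$truth, "dglc", cfg_lo)
  st_hi <- simulate_barseq_counts(sim$pool, sim$truth, "dglc", cfg_hi)
  m_lo <- mean(abs(strain_fitness_table(st_lo$t0, st_lo$counts)$score))
  m_hi <- mean(abs(strain_fitness_table(st_hi$t0, st_hi$counts)$score))
  expect_lt(m_hi, m_lo)
  expect_lt(m_hi, 0.1)
})

test_that("RNA-seq simulation is calibrated under the null and powered when induced", {
  lengths_of <- function(genes) setNames(genes$length_nt, genes$gene_id)

  # null calibration: BH q < 0.05 rate stays near nominal across 20 seeds
  rates <- vapply(1:20, function(s) {
    cfg <- sim_config(n_genes = 200, seed = s)
    sim <- simulate_pool(cfg)
    rna <- simulate_rnaseq_counts(sim$genes, cfg)
    expr <- expression_table(rna$counts, lengths_of(sim$genes),
                             rna$conditions)
    mean(expr$genes$q < 0.05)
  }, numeric(1))
  expect_lte(mean(rates), 0.05 * 1.5)

  # a 50-fold induced gene at dispersion 0.05 passes the expression filter
  hits <- vapply(1:20, function(s) {
    cfg <- sim_config(n_genes = 100, rnaseq_dispersion = 0.05,
                      induced_genes = list(gene_0001 = c(dgalua = 50)),
                      seed = 100 + s)
    sim <- simulate_pool(cfg)
    rna <- simulate_rnaseq_counts(sim$genes, cfg)
    expr <- expression_table(rna$counts, lengths_of(sim$genes),
                             rna$conditions)
    "gene_0001" %in% prefilter_genes(expr)
  }, logical(1))
  expect_gte(mean(hits), 0.95)

  # zero-baseline genes -> all-zero counts
  cfg <- sim_config(n_genes = 5, seed = 2)
  sim <- simulate_pool(cfg)
  rna_zero <- simulate_rnaseq_counts(sim$genes, cfg,
                                     baseline_meanlog = -Inf)
  expect_true(all(rna_zero$counts == 0))
})

test_that("simulated FASTQ round-trips through the counter", {
  pool <- data.frame(
    barcode = c(strrep("A", 20), strrep("C", 20)),
    scaffold = "s1", position = c(1L, 2L), strand = "+",
    assigned_genes = "", stringsAsFactors = FALSE)
  fl <- flank_config()
  fq <- withr::local_tempfile(fileext = ".fastq")
  res <- simulate_fastq(pool, c(0.5, 0.5), 1000, fl, fq, seed = 9)
  drawn <- attr(res, "drawn")
  counts <- count_barcodes(fq, pool, fl)
  expect_equal(as.integer(counts[, 1]), as.integer(drawn))
  expect_equal(sum(counts), 1000)
  expect_equal(unname(attr(counts, "unextractable")[1]), 0L)

  # empty FASTQ is valid
  fq0 <- withr::local_tempfile(fileext = ".fastq")
  simulate_fastq(pool, c(0.5, 0.5), 0, fl, fq0, seed = 9)
  c0 <- count_barcodes(fq0, pool, fl)
  expect_true(all(c0 == 0))

  # truncated reads lose their 3' flank and are rejected by extraction
  fq_t <- withr::local_tempfile(fileext = ".fastq")
  simulate_fastq(pool, c(0.5, 0.5), 5000, fl, fq_t, seed = 10,
                 truncate_rate = 0.1)
  ct <- count_barcodes(fq_t, pool, fl)
  frac <- sum(ct) / 5000
  expect_gt(frac, 0.87)
  expect_lt(frac, 0.93)
})

test_that("Michaelis-Menten assay generator matches the analytic curve", {
  r <- simulate_mm_assay(7, 553, c(0, 7), noise_sd = 0)
  expect_equal(r$v[r$S == 0], 0)
  expect_equal(r$v[r$S == 7], 276.5)  # half saturation at S = Km
  rn <- simulate_mm_assay(7, 553, c(1, 5, 20), noise_sd = 5, seed = 4)
  rn2 <- simulate_mm_assay(7, 553, c(1, 5, 20), noise_sd = 5, seed = 4)
  expect_identical(rn, rn2)
  expect_true(all(rn$v >= 0))
})
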