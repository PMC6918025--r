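mk_gf <- function(condition, gene_id, fitness, variance = 0.05) {
  data.frame(gene_id = gene_id, condition = condition, fitness = fitness,
             variance = variance, t = fitness / sqrt(variance),
             n_barcodes = 3L, n_observations = 9L, stringsAsFactors = FALSE)
}

test_that("expression arm applies the q, FPKM, and per-reference fold rules", {
  th <- filter_thresholds()
  # strongly induced transporter-like profile passes against both references
  expect_true(expression_pass(4605, cbind(78, 23), q = 0.01, th))
  # below the minimum FPKM
  expect_false(expression_pass(4, cbind(1, 1), q = 0.01, th))
  # fails the fold rule against one reference only (100/60 = 1.67)
  expect_false(expression_pass(100, cbind(60, 10), q = 0.01, th))
  # same FPKM but not significant
  expect_false(expression_pass(4605, cbind(78, 23), q = 0.2, th))
  # q = NULL skips the significance rule (pre-filtered published tables)
  expect_true(expression_pass(4605, cbind(78, 23), q = NULL, th))
})

test_that("fitness arm requires both rules against every reference", {
  th <- filter_thresholds()
  gf_t <- mk_gf("dgalua", c("g1", "g2", "g3"), c(-4.0, 0, -0.8))
  gf_r1 <- mk_gf("gly", c("g1", "g2", "g3"), c(0.0, 0, 0.0))
  gf_r2 <- mk_gf("dglc", c("g1", "g2", "g3"), c(0.3, 0, 0.1))
  rel <- list(relative_fitness(gf_t, gf_r1), relative_fitness(gf_t, gf_r2))
  fp <- fitness_pass(rel, th)
  # g1: rel scores -4.0 / -4.3 with tiny variance -> passes
  expect_true(fp$pass[fp$gene_id == "g1"])
  # g2: neutral everywhere
  expect_false(fp$pass[fp$gene_id == "g2"])
  # g3: rel scores -0.8 / -0.9 miss the -1 cutoff
  expect_false(fp$pass[fp$gene_id == "g3"])
})

synthetic_candidate_run <- function(seed, n_genes = 300) {
  planted <- c("gene_0001", "gene_0002", "gene_0003", "gene_0004")
  eff <- setNames(lapply(planted, function(g) c(dgalua = -0.8)), planted)
  ind <- setNames(lapply(planted, function(g) c(dgalua = 50)), planted)
  cfg <- sim_config(n_genes = n_genes, depth_per_sample = 5e5,
                    fitness_effects = eff, induced_genes = ind, seed = seed)
  sim <- simulate_pool(cfg)
  gf <- lapply(cfg$conditions, function(cc) {
    bs <- simulate_barseq_counts(sim$pool, sim$truth, cc, cfg)
    score_gene_fitness(bs$t0, bs$counts, sim$pool, cc)
  })
  names(gf) <- cfg$conditions
  rna <- simulate_rnaseq_counts(sim$genes, cfg)
  expr <- expression_table(rna$counts,
                           setNames(sim$genes$length_nt, sim$genes$gene_id),
                           rna$conditions)
  list(expr = expr, gf = gf, planted = planted)
}

test_that("candidate table recovers planted pathway genes and flags the rest", {
  run <- synthetic_candidate_run(seed = 19)
  ct <- candidate_table(run$expr, run$gf, "dgalua", c("dglc", "gly"))
  expect_setequal(ct$candidates$gene_id, run$planted)
  expect_equal(nrow(ct$extended), 300)
  expect_true(all(c("pass_expression", "pass_fitness", "evaluable",
                    "rel_score_gly", "rel_t_dglc") %in% names(ct$extended)))
  # every passing row satisfies both arms
  expect_true(all(ct$candidates$pass_expression & ct$candidates$pass_fitness))

  # monotonicity: tightening any threshold never adds candidates
  tighter <- list(
    filter_thresholds(min_fpkm = 50),
    filter_thresholds(min_fold = 10),
    filter_thresholds(max_q = 0.001),
    filter_thresholds(max_rel_fitness = -3),
    filter_thresholds(max_rel_t = -20))
  for (th in tighter) {
    ct2 <- candidate_table(run$expr, run$gf, "dgalua", c("dglc", "gly"), th)
    expect_true(all(ct2$candidates$gene_id %in% ct$candidates$gene_id))
  }

  # an impossible fold threshold empties the report
  th_inf <- filter_thresholds(min_fold = Inf)
  ct3 <- candidate_table(run$expr, run$gf, "dgalua", c("dglc", "gly"), th_inf)
  expect_equal(nrow(ct3$candidates), 0)

  # gene input order does not matter
  expr_rev <- run$expr
  rev_idx <- rev(seq_len(nrow(expr_rev$genes)))
  expr_rev$genes <- expr_rev$genes[rev_idx, ]
  expr_rev$means <- expr_rev$means[rev(rownames(run$expr$means)), ]
  expr_rev$fpkm <- expr_rev$fpkm[rev(rownames(run$expr$fpkm)), ]
  ct_rev <- candidate_table(expr_rev, run$gf, "dgalua", c("dglc", "gly"))
  expect_equal(ct_rev$candidates$gene_id, ct$candidates$gene_id)
})

test_that("genes without fitness data are flagged not evaluable, never called", {
  run <- synthetic_candidate_run(seed = 23, n_genes = 100)
  gf_missing <- lapply(run$gf, function(g) g[g$gene_id != "gene_0001", ])
  expect_message(
    ct <- candidate_table(run$expr, gf_missing, "dgalua", c("dglc", "gly")),
    "not evaluable")
  row <- ct$extended[ct$extended$gene_id == "gene_0001", ]
  expect_false(row$evaluable)
  expect_false(row$candidate)
  expect_false("gene_0001" %in% ct$candidates$gene_id)

  # disjoint gene universes are an error
  gf_alien <- lapply(run$gf, function(g) {
    g$gene_id <- paste0("other_", g$gene_id); g
  })
  expect_error(candidate_table(run$expr, gf_alien, "dgalua",
                               c("dglc", "gly")), "no gene shared")
})

test_that("scatter export is complete and centers the neutral cloud at the origin", {
  cfg <- sim_config(n_genes = 150, depth_per_sample = 1e6, seed = 29)
  sim <- simulate_pool(cfg)
  gf <- lapply(c("dgalua", "gly"), function(cc) {
    bs <- simulate_barseq_counts(sim$pool, sim$truth, cc, cfg)
    score_gene_fitness(bs$t0, bs$counts, sim$pool, cc)
  })
  names(gf) <- c("dgalua", "gly")
  rna <- simulate_rnaseq_counts(sim$genes, cfg)
  expr <- expression_table(rna$counts,
                           setNames(sim$genes$length_nt, sim$genes$gene_id),
                           rna$conditions)
  sc <- scatter_export(expr, gf$dgalua, gf$gly, "dgalua", "gly")
  expect_equal(nrow(sc),
               length(intersect(expr$genes$gene_id, gf$dgalua$gene_id)))
  expect_true(all(is.finite(sc$dlog2_expression)))
  expect_true(all(is.finite(sc$rel_score)))
  expect_lt(mean(abs(sc$rel_score)), 0.1)
  expect_lt(abs(mean(sc$dlog2_expression)), 0.2)
})
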