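# Independent straight-line reimplementation of the fitness math, written
# as explicit per-element loops so it shares no code path with the package.
# Given paired time-zero / condition count matrices and a barcode -> gene
# lookup, it recomputes raw scores, per-sample normalization, weighted gene
# fitness and the variance-floor T-statistic from first principles.

oracle_strain_scores <- function(t0, counts, pc = 1) {
  scores <- matrix(NA_real_, nrow(t0), ncol(t0), dimnames = dimnames(counts))
  for (r in seq_len(ncol(t0))) {
    N0 <- sum(t0[, r])
    N <- sum(counts[, r])
    sc <- if (N > 0) N0 / N else 1
    raw <- numeric(nrow(t0))
    for (b in seq_len(nrow(t0))) {
      raw[b] <- log2((counts[b, r] * sc + pc) / (t0[b, r] + pc))
    }
    scores[, r] <- raw - mean(raw)
  }
  scores
}

oracle_gene_fitness <- function(t0, counts, gene_of_barcode, pc = 1) {
  scores <- oracle_strain_scores(t0, counts, pc)
  genes <- sort(unique(gene_of_barcode[!is.na(gene_of_barcode)]))
  out <- data.frame(gene_id = genes, fitness = NA_real_,
                    variance = NA_real_, t = NA_real_,
                    stringsAsFactors = FALSE)
  for (gi in seq_along(genes)) {
    sw <- 0; swx <- 0
    ws <- c(); xs <- c(); vs <- c()
    for (b in seq_len(nrow(t0))) {
      if (is.na(gene_of_barcode[b]) || gene_of_barcode[b] != genes[gi]) next
      for (r in seq_len(ncol(t0))) {
        w <- 2 / (1 / (t0[b, r] + pc) + 1 / (counts[b, r] + pc))
        ws <- c(ws, w)
        xs <- c(xs, scores[b, r])
        vs <- c(vs, 1 / (t0[b, r] + pc) + 1 / (counts[b, r] + pc))
      }
    }
    fit <- sum(ws * xs) / sum(ws)
    v_count <- (1 / log(2))^2 * sum(ws^2 * vs) / sum(ws)^2
    m <- length(xs)
    v_emp <- 0
    if (m >= 2) v_emp <- sum(ws * (xs - fit)^2) / (sum(ws) * (m - 1))
    v <- max(v_count, v_emp)
    out$fitness[gi] <- fit
    out$variance[gi] <- v
    out$t[gi] <- if (v > 0) fit / sqrt(v) else 0
  }
  out
}

# Random small instance shared by the oracle-equivalence tests: n_barcodes
# barcodes over a few genes (some intergenic), counts <= max_count.
random_fitness_instance <- function(seed, n_barcodes = 10, n_reps = 2,
                                    max_count = 1e4) {
  set.seed(seed)
  barcodes <- sprintf("BC%02d", seq_len(n_barcodes))
  genes <- c(sample(c("gA", "gB", "gC"), n_barcodes - 1, replace = TRUE),
             NA_character_)
  t0 <- matrix(sample(0:max_count, n_barcodes * n_reps, replace = TRUE),
               n_barcodes, n_reps,
               dimnames = list(barcodes, paste0("t0_", seq_len(n_reps))))
  counts <- matrix(sample(0:max_count, n_barcodes * n_reps, replace = TRUE),
                   n_barcodes, n_reps,
                   dimnames = list(barcodes, paste0("cond_", seq_len(n_reps))))
  list(t0 = t0, counts = counts, gene_of_barcode = genes,
       pool = data.frame(barcode = barcodes, scaffold = "s1",
                         position = seq_len(n_barcodes), strand = "+",
                         assigned_genes = ifelse(is.na(genes), "", genes),
                         stringsAsFactors = FALSE))
}
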