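# Strain fitness scores, per-sample normalization, depth-weighted gene
# aggregation, the variance-floor T-statistic, and between-condition
# relative fitness.
#
# Model. A strain's fitness score is the log2 ratio of its barcode count in
# the grown condition sample versus the time-zero reference, with the
# condition sample depth-scaled to the time-zero library size and a
# pseudocount guarding zeros:
#
#   score_b = log2((n_b * N0/N + pc) / (n0_b + pc))
#
# Scores are normalized to mean zero per sample (most insertions are
# phenotypically neutral, so the pool average anchors zero). Gene fitness is
# a weighted mean of all observations (barcodes x replicates) of a gene,
# with weights the harmonic means of the pseudocounted depths
#
#   w_i = 2 / (1/(n0_i + pc) + 1/(n_i + pc))
#
# so deeply sequenced strains dominate. Significance uses a T-statistic
# t = fitness / sqrt(V) whose variance is floored at the Poisson count-noise
# level:
#
#   V = max(V_count, V_emp)
#   V_count = (1/ln2)^2 * sum(w_i^2 * (1/(n0_i+pc) + 1/(n_i+pc))) / (sum w_i)^2
#   V_emp   = sum(w_i * (score_i - fitness)^2) / ((sum w_i) * (m - 1))
#
# V_count is the delta-method variance of the weighted-mean log2 ratio under
# Poisson counting noise; V_emp measures the observed consistency between
# barcodes and between replicates. Scores are deliberately not scaled by the
# number of generations.

#' Raw strain fitness scores for one sample
#'
#' @param n0 Named (by barcode) nonnegative time-zero counts.
#' @param n Named condition-sample counts over the same barcodes.
#' @param pseudocount Pseudocount added to both counts (default 1).
#' @param scale_depth Scale `n` to the time-zero library size before the
#'   ratio (default `TRUE`).
#' @return Named numeric vector of raw (un-normalized) log2-ratio scores.
#' @export
strain_fitness <- function(n0, n, pseudocount = 1, scale_depth = TRUE) {
  stopifnot(pseudocount > 0, all(n0 >= 0), all(n >= 0))
  if (!is.null(names(n0)) || !is.null(names(n))) {
    if (is.null(names(n0)) || is.null(names(n)) ||
        !setequal(names(n0), names(n))) {
      stop("barcode sets of n0 and n do not match")
    }
    n <- n[names(n0)]
  } else if (length(n0) != length(n)) {
    stop("barcode sets of n0 and n do not match")
  }
  scale <- if (scale_depth && sum(n) > 0) sum(n0) / sum(n) else 1
  log2((n * scale + pseudocount) / (n0 + pseudocount))
}

#' Normalize fitness scores to zero mean within a sample
#'
#' @param scores Numeric vector of raw scores from one sample.
#' @return Scores minus their mean.
#' @export
normalize_fitness <- function(scores) {
  stopifnot(length(scores) >= 1)
  scores - mean(scores)
}

#' Per-strain fitness table across replicates
#'
#' Computes normalized strain scores for each replicate of a condition
#' against its paired time-zero sample, retaining the raw counts needed for
#' downstream weighting.
#'
#' @param t0 Barcode x replicate time-zero count matrix.
#' @param counts Barcode x replicate condition count matrix (same barcodes,
#'   same number of columns).
#' @param pseudocount Pseudocount (default 1).
#' @return data.frame with columns `barcode`, `replicate`, `n0`, `n`,
#'   `score` (normalized).
#' @export
strain_fitness_table <- function(t0, counts, pseudocount = 1) {
  stopifnot(nrow(t0) == nrow(counts), ncol(t0) == ncol(counts))
  if (!identical(rownames(t0), rownames(counts))) {
    stop("barcode sets of t0 and counts do not match")
  }
  reps <- lapply(seq_len(ncol(counts)), function(r) {
    raw <- strain_fitness(stats::setNames(t0[, r], rownames(t0)),
                          stats::setNames(counts[, r], rownames(counts)),
                          pseudocount = pseudocount)
    data.frame(barcode = rownames(counts), replicate = r,
               n0 = as.numeric(t0[, r]), n = as.numeric(counts[, r]),
               score = as.numeric(normalize_fitness(raw)),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, reps)
}

#' Observation weights: harmonic mean of pseudocounted depths
#'
#' @param n0,n Counts of an observation.
#' @param pseudocount Pseudocount (default 1).
#' @return Positive weights.
#' @export
fitness_weight <- function(n0, n, pseudocount = 1) {
  2 / (1 / (n0 + pseudocount) + 1 / (n + pseudocount))
}

#' T-statistic for one gene's observations
#'
#' Variance-floor consistency statistic: the weighted-mean fitness divided
#' by the square root of the larger of the count-noise variance and the
#' empirical between-observation variance (see the module header for the
#' formulas).
#'
#' @param score Normalized scores of the gene's observations
#'   (barcodes x replicates).
#' @param n0,n The observations' counts.
#' @param pseudocount Pseudocount (default 1).
#' @return List with `fitness`, `variance`, `t`, `n_observations`.
#' @export
gene_t_statistic <- function(score, n0, n, pseudocount = 1) {
  m <- length(score)
  stopifnot(m >= 1, length(n0) == m, length(n) == m)
  w <- fitness_weight(n0, n, pseudocount)
  sw <- sum(w)
  fitness <- sum(w * score) / sw
  v_count <- (1 / log(2))^2 *
    sum(w^2 * (1 / (n0 + pseudocount) + 1 / (n + pseudocount))) / sw^2
  v_emp <- if (m >= 2) sum(w * (score - fitness)^2) / (sw * (m - 1)) else 0
  v <- max(v_count, v_emp)
  if (v == 0) {
    warning("zero variance estimate; reporting t = 0")
    t <- 0
  } else {
    t <- fitness / sqrt(v)
  }
  list(fitness = fitness, variance = v, t = t, n_observations = m)
}

#' Gene-level fitness from strain observations
#'
#' Aggregates all observations (barcodes x replicates) of each gene into a
#' weighted-mean fitness, its variance, and the T-statistic. Strains not
#' assigned to any gene are excluded; genes with no observation are omitted
#' (with a message).
#'
#' @param strain_tab Output of [strain_fitness_table()].
#' @param gene_map data.frame with columns `barcode`, `gene_id`
#'   (see [pool_gene_map()]).
#' @param pseudocount Pseudocount (default 1).
#' @param condition Optional condition label copied into the output.
#' @return data.frame with columns `gene_id`, `condition`, `fitness`,
#'   `variance`, `t`, `n_barcodes`, `n_observations`, ordered by `gene_id`.
#' @export
gene_fitness <- function(strain_tab, gene_map, pseudocount = 1,
                         condition = NA_character_) {
  obs <- merge(strain_tab, gene_map, by = "barcode")
  if (nrow(obs) == 0) {
    message("no scored barcode maps to any gene")
    return(data.frame(gene_id = character(), condition = character(),
                      fitness = numeric(), variance = numeric(),
                      t = numeric(), n_barcodes = integer(),
                      n_observations = integer(), stringsAsFactors = FALSE))
  }
  parts <- split(obs, obs$gene_id)
  rows <- lapply(parts, function(d) {
    st <- gene_t_statistic(d$score, d$n0, d$n, pseudocount)
    data.frame(gene_id = d$gene_id[1], condition = condition,
               fitness = st$fitness, variance = st$variance, t = st$t,
               n_barcodes = length(unique(d$barcode)),
               n_observations = st$n_observations,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out[order(out$gene_id), , drop = FALSE]
}

#' Relative fitness between two conditions
#'
#' For each gene present in both tables, the difference of fitness scores
#' and the corresponding T-statistic
#' `(f_A - f_B) / sqrt(V_A + V_B)`.
#'
#' @param gf_a,gf_b [gene_fitness()] tables for conditions A and B. They
#'   must carry different `condition` labels.
#' @return data.frame with `gene_id`, `rel_score`, `rel_t` for genes shared
#'   by both tables.
#' @export
relative_fitness <- function(gf_a, gf_b) {
  ca <- unique(gf_a$condition)
  cb <- unique(gf_b$condition)
  if (length(ca) == 1 && length(cb) == 1 && !is.na(ca) && identical(ca, cb)) {
    stop("relative fitness requires two different conditions, got ", ca)
  }
  shared <- merge(gf_a, gf_b, by = "gene_id", suffixes = c("_a", "_b"))
  data.frame(gene_id = shared$gene_id,
             rel_score = shared$fitness_a - shared$fitness_b,
             rel_t = (shared$fitness_a - shared$fitness_b) /
               sqrt(shared$variance_a + shared$variance_b),
             stringsAsFactors = FALSE)
}

#' Full fitness pipeline for one condition
#'
#' Convenience wrapper: strain scores against paired time-zero samples,
#' normalization, and gene aggregation.
#'
#' @param t0,counts Barcode x replicate count matrices (see
#'   [strain_fitness_table()]).
#' @param pool Pool data.frame with `assigned_genes` filled in.
#' @param condition Condition label for the output.
#' @param pseudocount Pseudocount (default 1).
#' @return A [gene_fitness()] table.
#' @export
score_gene_fitness <- function(t0, counts, pool, condition,
                               pseudocount = 1) {
  st <- strain_fitness_table(t0, counts, pseudocount)
  gene_fitness(st, pool_gene_map(pool), pseudocount, condition)
}
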