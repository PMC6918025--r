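# Synthetic pools, BarSeq counts, RNA-seq counts, barcode FASTQ, and
# enzyme-assay rate tables with known ground truth.
#
# The generators emulate the study design the package analyses: a barcoded
# random T-DNA insertion library grown competitively for ~6 generations on
# one of three carbon sources (d-galUA, d-glc, glycerol), sequenced by
# barcode amplicons; and three-condition, three-replicate bulk RNA-seq.

#' Simulation configuration
#'
#' Bundles the parameters of the synthetic study design. Defaults mirror the
#' profiled experiment: three carbon sources, three biological replicates,
#' growth for six generations, and desk-scale library complexity and depth.
#'
#' @param n_genes Number of genes on the synthetic scaffold.
#' @param barcodes_per_gene_mean Poisson mean of barcoded insertions per gene
#'   (a minimum of one is enforced).
#' @param intergenic_fraction Fraction of the final pool made of neutral
#'   intergenic barcodes, in `[0, 1)`.
#' @param generations Generations of competitive growth (default 6).
#' @param depth_per_sample Total sequencing reads per sample.
#' @param n_replicates Biological replicates per condition.
#' @param conditions Condition names; the first is conventionally the
#'   treatment of interest.
#' @param fitness_effects Named list: `gene_id` -> named numeric vector of
#'   per-generation fitness effects by condition (0 = neutral).
#' @param induced_genes Named list: `gene_id` -> named numeric vector of
#'   expression fold inductions (>= 1) by condition.
#' @param rnaseq_dispersion Negative-binomial dispersion of RNA-seq counts.
#' @param abundance_sigma Log-normal sd of time-zero strain abundances.
#' @param seed Integer seed making every generator deterministic.
#' @return A list of class `"sim_config"`.
#' @export
sim_config <- function(n_genes = 500,
                       barcodes_per_gene_mean = 3,
                       intergenic_fraction = 0.2,
                       generations = 6,
                       depth_per_sample = 1e6,
                       n_replicates = 3,
                       conditions = c("dgalua", "dglc", "gly"),
                       fitness_effects = list(),
                       induced_genes = list(),
                       rnaseq_dispersion = 0.05,
                       abundance_sigma = 1,
                       seed = 1) {
  stopifnot(n_genes >= 1, barcodes_per_gene_mean > 0,
            intergenic_fraction >= 0, intergenic_fraction < 1,
            generations > 0, depth_per_sample >= 1, n_replicates >= 1,
            length(conditions) >= 1, rnaseq_dispersion > 0,
            abundance_sigma > 0)
  structure(list(n_genes = as.integer(n_genes),
                 barcodes_per_gene_mean = barcodes_per_gene_mean,
                 intergenic_fraction = intergenic_fraction,
                 generations = generations,
                 depth_per_sample = as.integer(depth_per_sample),
                 n_replicates = as.integer(n_replicates),
                 conditions = conditions,
                 fitness_effects = fitness_effects,
                 induced_genes = induced_genes,
                 rnaseq_dispersion = rnaseq_dispersion,
                 abundance_sigma = abundance_sigma,
                 seed = as.integer(seed)),
            class = "sim_config")
}

random_barcodes <- function(n, length = 20) {
  bc <- character(0)
  while (length(bc) < n) {
    need <- n - length(bc)
    new <- vapply(seq_len(need), function(i) {
      paste(sample(BARCODE_ALPHABET, length, replace = TRUE), collapse = "")
    }, character(1))
    bc <- unique(c(bc, new))
  }
  bc[seq_len(n)]
}

effect_matrix <- function(ids, conditions, effects, default = 0) {
  m <- matrix(default, nrow = length(ids), ncol = length(conditions),
              dimnames = list(ids, conditions))
  for (g in intersect(names(effects), ids)) {
    v <- effects[[g]]
    m[g, intersect(names(v), conditions)] <-
      v[intersect(names(v), conditions)]
  }
  m
}

#' Simulate a barcoded insertion pool with ground truth
#'
#' Tiles `n_genes` non-overlapping genes on one synthetic scaffold, drops
#' `max(1, Poisson)` barcoded insertions into each gene span, adds neutral
#' intergenic barcodes between genes, and draws log-normal time-zero strain
#' abundances.
#'
#' @param config A [sim_config()].
#' @return A list with elements `pool` (pool data.frame with
#'   `assigned_genes` filled in), `genes` (annotation data.frame), and
#'   `truth` (list: `gene_fitness` and `expression_fold` matrices gene x
#'   condition, `abundance` named barcode vector summing to 1).
#' @export
simulate_pool <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  gene_len <- 1500L
  gap <- 500L
  starts <- (seq_len(config$n_genes) - 1L) * (gene_len + gap) + gap + 1L
  genes <- data.frame(
    gene_id = sprintf("gene_%04d", seq_len(config$n_genes)),
    scaffold = "scaffold_1",
    start = starts,
    end = starts + gene_len - 1L,
    strand = rep(c("+", "-"), length.out = config$n_genes),
    length_nt = gene_len,
    description = "synthetic gene",
    stringsAsFactors = FALSE)

  k <- pmax(1L, stats::rpois(config$n_genes, config$barcodes_per_gene_mean))
  genic_pos <- unlist(lapply(seq_len(config$n_genes), function(i) {
    sample(seq(genes$start[i], genes$end[i]), k[i], replace = FALSE)
  }))
  n_genic <- sum(k)
  n_inter <- round(n_genic * config$intergenic_fraction /
                     (1 - config$intergenic_fraction))
  inter_pos <- integer(0)
  if (n_inter > 0) {
    gaps <- unlist(lapply(seq_len(config$n_genes), function(i) {
      seq(genes$start[i] - gap, genes$start[i] - 1L)
    }))
    inter_pos <- sample(gaps, n_inter, replace = FALSE)
  }
  pos <- c(genic_pos, inter_pos)
  pool <- data.frame(
    barcode = random_barcodes(length(pos)),
    scaffold = "scaffold_1",
    position = as.integer(pos),
    strand = sample(c("+", "-"), length(pos), replace = TRUE),
    assigned_genes = "",
    stringsAsFactors = FALSE)
  pool <- assign_insertions(pool, genes)
  attr(pool, "genome_name") <- "synthetic"

  ab <- stats::rlnorm(nrow(pool), 0, config$abundance_sigma)
  ab <- ab / sum(ab)
  names(ab) <- pool$barcode

  truth <- list(
    gene_fitness = effect_matrix(genes$gene_id, config$conditions,
                                 config$fitness_effects, 0),
    expression_fold = effect_matrix(genes$gene_id, config$conditions,
                                    config$induced_genes, 1),
    abundance = ab)
  list(pool = pool, genes = genes, truth = truth)
}

#' Simulate BarSeq count matrices for one condition
#'
#' Strains grow for `generations` doublings; a strain carrying an insertion
#' in a gene with per-generation fitness `f` multiplies its abundance by
#' `2^(g * (1 + f))`, so for a rare strain the expected raw log2 count ratio
#' against time zero is about `g * f` relative to the neutral background.
#' Per replicate, a time-zero sample and a condition sample are drawn
#' multinomially at the configured depth.
#'
#' @param pool,truth,genes Elements of a [simulate_pool()] result.
#' @param condition Condition name (must be a column of the truth matrices).
#' @param config The [sim_config()] used to build the pool.
#' @param seed Seed for the count draws; defaults to the config seed offset
#'   by the condition index so conditions decorrelate.
#' @return List with matrices `t0` and `counts` (barcode x replicate,
#'   columns named `t0_1.. / <condition>_1..`); every column sums to
#'   `depth_per_sample`.
#' @export
simulate_barseq_counts <- function(pool, truth, condition, config,
                                   seed = NULL) {
  stopifnot(inherits(config, "sim_config"))
  if (!condition %in% colnames(truth$gene_fitness)) {
    stop("unknown condition: ", condition)
  }
  if (is.null(seed)) {
    seed <- config$seed + 1000L * match(condition, config$conditions)
  }
  set.seed(seed)
  a0 <- truth$abundance[pool$barcode]
  # per-barcode fitness: mean of its assigned genes' effects, 0 if intergenic
  f <- vapply(pool$assigned_genes, function(a) {
    if (is.na(a) || a == "") return(0)
    mean(truth$gene_fitness[strsplit(a, ";", fixed = TRUE)[[1]], condition])
  }, numeric(1), USE.NAMES = FALSE)
  a_end <- a0 * 2^(config$generations * (1 + f))
  a_end <- a_end / sum(a_end)

  reps <- seq_len(config$n_replicates)
  t0 <- vapply(reps, function(r) {
    stats::rmultinom(1, config$depth_per_sample, a0)[, 1]
  }, numeric(nrow(pool)))
  cnt <- vapply(reps, function(r) {
    stats::rmultinom(1, config$depth_per_sample, a_end)[, 1]
  }, numeric(nrow(pool)))
  dimnames(t0) <- list(pool$barcode, paste0("t0_", reps))
  dimnames(cnt) <- list(pool$barcode, paste0(condition, "_", reps))
  list(t0 = t0, counts = cnt)
}

#' Simulate a three-condition RNA-seq count table
#'
#' Baseline per-gene expression means are log-normal; a condition's mean is
#' the baseline times the gene's induced fold for that condition; counts are
#' negative binomial with a single global dispersion.
#'
#' @param genes Gene annotation data.frame.
#' @param config A [sim_config()].
#' @param baseline_meanlog,baseline_sdlog Log-normal parameters of the
#'   baseline expected counts (defaults give a median of ~150 counts).
#' @param seed Seed; defaults to `config$seed + 777`.
#' @return List with `counts` (gene x sample integer matrix, columns
#'   `<condition>_<replicate>`), `conditions` (condition label per column),
#'   `libsizes` (column sums), and `baseline` (per-gene expected counts).
#' @export
simulate_rnaseq_counts <- function(genes, config,
                                   baseline_meanlog = 5,
                                   baseline_sdlog = 1.5,
                                   seed = NULL) {
  stopifnot(inherits(config, "sim_config"))
  if (is.null(seed)) seed <- config$seed + 777L
  set.seed(seed)
  baseline <- stats::rlnorm(nrow(genes), baseline_meanlog, baseline_sdlog)
  names(baseline) <- genes$gene_id
  fold <- effect_matrix(genes$gene_id, config$conditions,
                        config$induced_genes, 1)
  samples <- expand.grid(rep = seq_len(config$n_replicates),
                         condition = config$conditions,
                         stringsAsFactors = FALSE)
  counts <- vapply(seq_len(nrow(samples)), function(s) {
    mu <- baseline * fold[, samples$condition[s]]
    stats::rnbinom(length(mu), mu = mu, size = 1 / config$rnaseq_dispersion)
  }, numeric(nrow(genes)))
  dimnames(counts) <- list(genes$gene_id,
                           paste0(samples$condition, "_", samples$rep))
  list(counts = counts, conditions = samples$condition,
       libsizes = colSums(counts), baseline = baseline)
}

#' Write a synthetic barcode-amplicon FASTQ file
#'
#' Each read is `pre_flank + barcode + post_flank`, padded with random
#' nucleotides to `read_length`, with constant quality. Barcodes are drawn
#' by abundance. A fraction of reads can be truncated right after the
#' barcode (before the 3' flank), emulating short amplicons that the
#' counter must reject.
#'
#' @param pool Pool data.frame.
#' @param abundances Named barcode probabilities (normalized internally).
#' @param depth Number of reads.
#' @param flanks A [flank_config()].
#' @param path Output FASTQ path.
#' @param seed Integer seed.
#' @param read_length Total read length (default: flanks + barcode + 10).
#' @param truncate_rate Fraction of reads cut immediately after the barcode.
#' @return `path`, invisibly. The drawn per-barcode read counts are attached
#'   as attribute `"drawn"` of the return value.
#' @export
simulate_fastq <- function(pool, abundances, depth, flanks, path, seed = 1,
                           read_length = NULL, truncate_rate = 0) {
  stopifnot(depth >= 0, truncate_rate >= 0, truncate_rate <= 1)
  set.seed(seed)
  p <- if (is.null(names(abundances))) {
    stopifnot(length(abundances) == nrow(pool))
    abundances
  } else {
    abundances[pool$barcode]
  }
  p <- p / sum(p)
  bl <- flanks$barcode_length
  min_len <- nchar(flanks$pre_flank) + bl + nchar(flanks$post_flank)
  if (is.null(read_length)) read_length <- min_len + 10L
  stopifnot(read_length >= min_len)

  if (depth == 0) {
    writeLines(character(0), path)
    out <- path
    attr(out, "drawn") <- stats::setNames(integer(nrow(pool)), pool$barcode)
    return(invisible(out))
  }
  drawn <- stats::rmultinom(1, depth, p)[, 1]
  idx <- sample(rep.int(seq_len(nrow(pool)), drawn))
  seqs <- paste0(flanks$pre_flank, pool$barcode[idx], flanks$post_flank)
  pad_n <- read_length - min_len
  if (pad_n > 0) {
    pad <- vapply(seq_len(depth), function(i) {
      paste(sample(BARCODE_ALPHABET, pad_n, replace = TRUE), collapse = "")
    }, character(1))
    seqs <- paste0(seqs, pad)
  }
  if (truncate_rate > 0) {
    cut <- stats::runif(depth) < truncate_rate
    seqs[cut] <- substr(seqs[cut], 1, nchar(flanks$pre_flank) + bl)
  }
  qual <- vapply(nchar(seqs), function(n) strrep("I", n), character(1))
  rec <- paste0("@read_", seq_len(depth), "\n", seqs, "\n+\n", qual)
  writeLines(rec, path)
  out <- path
  attr(out, "drawn") <- drawn
  invisible(out)
}

#' Simulate a Michaelis-Menten assay rate table
#'
#' @param Km Half-saturation constant (mM).
#' @param Vmax Maximal specific activity (nkat/mg).
#' @param substrate_concs Substrate concentrations (mM).
#' @param noise_sd Gaussian noise sd on rates (nkat/mg); rates are truncated
#'   at zero.
#' @param seed Integer seed (only used when `noise_sd > 0`).
#' @param replicates Technical replicates per concentration.
#' @return data.frame with columns `S`, `v`, `replicate`.
#' @export
simulate_mm_assay <- function(Km, Vmax, substrate_concs, noise_sd = 0,
                              seed = 1, replicates = 1) {
  stopifnot(Km > 0, Vmax > 0, all(substrate_concs >= 0), noise_sd >= 0)
  if (noise_sd > 0) set.seed(seed)
  S <- rep(substrate_concs, times = replicates)
  repl <- rep(seq_len(replicates), each = length(substrate_concs))
  v <- Vmax * S / (Km + S)
  if (noise_sd > 0) v <- pmax(0, v + stats::rnorm(length(v), 0, noise_sd))
  data.frame(S = S, v = v, replicate = repl)
}
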