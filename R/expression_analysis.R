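# FPKM computation, three-condition differential expression, and
# correlation-based hierarchical clustering of expression profiles.

#' FPKM from gene counts
#'
#' `FPKM = counts * 1e9 / (libsize * length)`, using each gene's transcript
#' length in nt and each sample's mapped-read total.
#'
#' @param counts Gene x sample integer matrix with gene ids as rownames.
#' @param lengths Named (by gene id) transcript lengths in nt.
#' @param libsizes Per-sample library sizes; defaults to column sums.
#' @return Numeric FPKM matrix with the same dimnames as `counts`.
#' @export
fpkm <- function(counts, lengths, libsizes = colSums(counts)) {
  missing_len <- setdiff(rownames(counts), names(lengths))
  if (length(missing_len) > 0) {
    stop("missing gene length for: ",
         paste(utils::head(missing_len, 5), collapse = ", "))
  }
  lengths <- lengths[rownames(counts)]
  stopifnot(all(lengths >= 1), all(libsizes >= 1),
            length(libsizes) == ncol(counts))
  sweep(counts * 1e9 / lengths, 2, libsizes, "/")
}

#' Per-gene differential-expression p values across conditions
#'
#' One-way ANOVA F-test on `log2(FPKM + 1)` across condition groups. This
#' is the package's stand-in differential test: the downstream quadrant
#' analysis only consumes fold changes and an adjusted p value, so a simple
#' calibrated test suffices. A gene with zero variance across all samples
#' gets `p = 1` by convention; a gene whose residual (within-condition)
#' variance is zero but whose group means differ gets `p = 0`.
#'
#' @param fpkm_mat Gene x sample FPKM matrix.
#' @param conditions Condition label per column (>= 2 conditions with >= 2
#'   replicates each).
#' @return Named numeric vector of p values in `[0, 1]`.
#' @export
differential_test <- function(fpkm_mat, conditions) {
  conditions <- as.factor(conditions)
  stopifnot(length(conditions) == ncol(fpkm_mat),
            nlevels(conditions) >= 2, all(table(conditions) >= 2))
  y <- log2(fpkm_mat + 1)
  p <- apply(y, 1, function(row) {
    if (stats::var(row) == 0) return(1)
    fit <- stats::oneway.test(row ~ conditions, var.equal = TRUE)
    pv <- fit$p.value
    if (is.nan(pv)) {
      # zero residual variance: group means differ exactly
      pv <- 0
    }
    pv
  })
  stats::setNames(as.numeric(p), rownames(fpkm_mat))
}

#' Benjamini-Hochberg adjusted q values
#'
#' @param p Numeric p values in `[0, 1]`.
#' @return Step-up adjusted q values (monotone in p rank, `q >= p`).
#' @export
bh_adjust <- function(p) {
  stopifnot(all(p >= 0 & p <= 1, na.rm = TRUE))
  stats::p.adjust(p, method = "BH")
}

#' Per-condition mean expression
#'
#' @param fpkm_mat Gene x sample FPKM matrix.
#' @param conditions Condition label per column.
#' @return Gene x condition matrix of means.
#' @export
condition_means <- function(fpkm_mat, conditions) {
  conditions <- as.character(conditions)
  stopifnot(length(conditions) == ncol(fpkm_mat))
  levels <- unique(conditions)
  m <- vapply(levels, function(cc) {
    rowMeans(fpkm_mat[, conditions == cc, drop = FALSE])
  }, numeric(nrow(fpkm_mat)))
  dimnames(m) <- list(rownames(fpkm_mat), levels)
  m
}

max_pairwise_fold <- function(means) {
  # max over condition pairs of high/low mean ratio; Inf where the low mean
  # is 0 and the high is not, 1 for an all-zero gene
  hi <- apply(means, 1, max)
  lo <- apply(means, 1, min)
  ifelse(hi == 0, 1, hi / lo)
}

#' Build an expression table from counts
#'
#' Computes FPKM, condition means, the maximal pairwise condition fold
#' change, ANOVA p values and BH q values for every gene.
#'
#' @param counts Gene x sample count matrix.
#' @param lengths Named transcript lengths (nt).
#' @param conditions Condition label per sample column.
#' @param libsizes Optional per-sample library sizes.
#' @return List with `fpkm` (matrix), `means` (gene x condition matrix), and
#'   `genes` (data.frame: `gene_id`, `max_fold`, `p`, `q`).
#' @export
expression_table <- function(counts, lengths, conditions,
                             libsizes = colSums(counts)) {
  fk <- fpkm(counts, lengths, libsizes)
  means <- condition_means(fk, conditions)
  p <- differential_test(fk, conditions)
  genes <- data.frame(gene_id = rownames(counts),
                      max_fold = max_pairwise_fold(means),
                      p = p, q = bh_adjust(p),
                      row.names = NULL, stringsAsFactors = FALSE)
  list(fpkm = fk, means = means, genes = genes)
}

#' Prefilter genes for clustering
#'
#' Keeps genes with significant differential expression (`q < max_q`),
#' non-trivial expression (maximal condition-mean FPKM >= `min_fpkm`), and a
#' maximal pairwise condition fold change >= `min_fold`.
#'
#' @param expr An [expression_table()] result.
#' @param min_fpkm,min_fold,max_q Filter thresholds (defaults 5, 2, 0.05).
#' @return Character vector of retained gene ids.
#' @export
prefilter_genes <- function(expr, min_fpkm = 5, min_fold = 2, max_q = 0.05) {
  g <- expr$genes
  keep <- g$q < max_q &
    apply(expr$means, 1, max) >= min_fpkm &
    g$max_fold >= min_fold
  g$gene_id[keep]
}

#' Cluster gene expression profiles
#'
#' Agglomerative clustering of gene profiles with distance
#' `1 - Pearson r` and average linkage, cut into `k` clusters. Genes are
#' ordered lexicographically by id before clustering so that tied merges
#' resolve reproducibly; returned labels are renumbered by decreasing
#' cluster size.
#'
#' @param fpkm_mat Gene x sample matrix of the retained genes; every row
#'   must have nonzero variance.
#' @param k Number of clusters (default 3).
#' @return Named integer vector of cluster labels in `1..k`, in the input
#'   gene order.
#' @export
cluster_genes <- function(fpkm_mat, k = 3) {
  stopifnot(k >= 1, nrow(fpkm_mat) >= k)
  v <- apply(fpkm_mat, 1, stats::var)
  if (any(v == 0)) {
    stop("zero-variance gene profile(s) reached clustering: ",
         paste(utils::head(rownames(fpkm_mat)[v == 0], 5), collapse = ", "))
  }
  ord <- order(rownames(fpkm_mat))
  m <- fpkm_mat[ord, , drop = FALSE]
  d <- stats::as.dist(1 - stats::cor(t(m)))
  tree <- stats::hclust(d, method = "average")
  labels <- stats::cutree(tree, k = k)
  # renumber by decreasing size (ties: by first occurrence)
  size_rank <- rank(-table(labels), ties.method = "first")
  labels <- as.integer(size_rank[as.character(labels)])
  names(labels) <- rownames(m)
  labels[rownames(fpkm_mat)]
}
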