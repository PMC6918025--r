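# Quadrant analysis: joint expression-induction and fitness-defect filter
# producing candidate-gene calls for a target condition against reference
# conditions.

#' Thresholds of the quadrant filter
#'
#' Defaults reproduce the published rule: significant differential
#' expression (adjusted p < 0.05), target-condition FPKM > 5, at least a
#' 2-fold expression increase over every reference condition, and a fitness
#' defect of relative fitness < -1 with relative T < -3 against every
#' reference.
#'
#' @param min_fpkm Minimum FPKM in the target condition (exclusive).
#' @param min_fold Minimum expression fold over each reference.
#' @param max_q Maximum BH-adjusted p value.
#' @param max_rel_fitness Maximum (most positive allowed) relative fitness.
#' @param max_rel_t Maximum relative T-statistic.
#' @return A list of class `"filter_thresholds"`.
#' @export
filter_thresholds <- function(min_fpkm = 5, min_fold = 2, max_q = 0.05,
                              max_rel_fitness = -1, max_rel_t = -3) {
  stopifnot(min_fold > 1, max_rel_fitness < 0, max_rel_t < 0)
  structure(list(min_fpkm = min_fpkm, min_fold = min_fold, max_q = max_q,
                 max_rel_fitness = max_rel_fitness, max_rel_t = max_rel_t),
            class = "filter_thresholds")
}

#' Expression arm of the quadrant filter
#'
#' A gene passes iff its adjusted p value is below `max_q` (skipped when `q`
#' is `NULL`, e.g. for pre-filtered published tables), its target-condition
#' FPKM exceeds `min_fpkm`, and its target FPKM is at least `min_fold` times
#' its FPKM in every reference condition.
#'
#' @param fpkm_target Numeric vector of target-condition mean FPKM.
#' @param fpkm_refs Matrix (genes x references) or vector of reference
#'   condition mean FPKM.
#' @param q Optional adjusted p values (`NULL` to skip the q test).
#' @param thresholds A [filter_thresholds()].
#' @return Logical vector.
#' @export
expression_pass <- function(fpkm_target, fpkm_refs, q = NULL,
                            thresholds = filter_thresholds()) {
  refs <- as.matrix(fpkm_refs)
  stopifnot(nrow(refs) == length(fpkm_target))
  fold_ok <- rowSums(fpkm_target < thresholds$min_fold * refs) == 0
  pass <- fpkm_target > thresholds$min_fpkm & fold_ok
  if (!is.null(q)) pass <- pass & q < thresholds$max_q
  pass
}

#' Fitness arm of the quadrant filter
#'
#' A gene passes iff against every reference condition its relative fitness
#' is below `max_rel_fitness` and its relative T-statistic below
#' `max_rel_t`.
#'
#' @param rel_list List of [relative_fitness()] tables (target vs each
#'   reference), aligned on the same `gene_id` universe.
#' @param thresholds A [filter_thresholds()].
#' @return data.frame `gene_id`, `pass` for genes present in all tables.
#' @export
fitness_pass <- function(rel_list, thresholds = filter_thresholds()) {
  stopifnot(length(rel_list) >= 1)
  shared <- Reduce(intersect, lapply(rel_list, function(r) r$gene_id))
  pass <- rep(TRUE, length(shared))
  for (rel in rel_list) {
    rel <- rel[match(shared, rel$gene_id), ]
    pass <- pass & rel$rel_score < thresholds$max_rel_fitness &
      rel$rel_t < thresholds$max_rel_t
  }
  data.frame(gene_id = shared, pass = pass, stringsAsFactors = FALSE)
}

#' Candidate-gene table from expression and fitness
#'
#' Combines the expression and fitness arms of the quadrant filter for a
#' target condition against one or more references. Genes must pass both
#' arms against every reference to be called candidates. Genes lacking
#' fitness data (e.g. essential genes absent from the insertion library)
#' are never called but are retained in the extended table flagged as not
#' evaluable.
#'
#' @param expr An [expression_table()] result.
#' @param gf_list Named list of [gene_fitness()] tables, one per condition;
#'   must contain `target` and every reference.
#' @param target Target condition name.
#' @param references Character vector of reference condition names.
#' @param thresholds A [filter_thresholds()].
#' @return List with `candidates` (rows passing both arms) and `extended`
#'   (all expression-universe genes with per-arm flags and metrics:
#'   FPKM means, fitness per condition, `rel_score_*`/`rel_t_*` per
#'   reference, `pass_expression`, `pass_fitness`, `evaluable`,
#'   `candidate`).
#' @export
candidate_table <- function(expr, gf_list, target, references,
                            thresholds = filter_thresholds()) {
  stopifnot(target %in% names(gf_list), all(references %in% names(gf_list)),
            target %in% colnames(expr$means),
            all(references %in% colnames(expr$means)))
  genes <- expr$genes$gene_id
  fit_genes <- Reduce(intersect, lapply(gf_list[c(target, references)],
                                        function(g) g$gene_id))
  if (length(intersect(genes, fit_genes)) == 0) {
    stop("no gene shared between the expression and fitness data")
  }

  out <- data.frame(gene_id = genes, stringsAsFactors = FALSE)
  for (cc in c(target, references)) {
    out[[paste0("fpkm_", cc)]] <- expr$means[genes, cc]
  }
  out$q <- expr$genes$q
  for (cc in c(target, references)) {
    gf <- gf_list[[cc]]
    out[[paste0("fitness_", cc)]] <- gf$fitness[match(genes, gf$gene_id)]
  }

  out$pass_expression <- expression_pass(
    expr$means[genes, target],
    expr$means[genes, references, drop = FALSE],
    q = expr$genes$q, thresholds = thresholds)

  rel_list <- lapply(references, function(ref) {
    relative_fitness(gf_list[[target]], gf_list[[ref]])
  })
  names(rel_list) <- references
  for (ref in references) {
    rel <- rel_list[[ref]]
    idx <- match(genes, rel$gene_id)
    out[[paste0("rel_score_", ref)]] <- rel$rel_score[idx]
    out[[paste0("rel_t_", ref)]] <- rel$rel_t[idx]
  }
  fp <- fitness_pass(rel_list, thresholds)
  idx <- match(genes, fp$gene_id)
  out$evaluable <- !is.na(idx)
  out$pass_fitness <- ifelse(out$evaluable, fp$pass[idx], FALSE)
  if (any(!out$evaluable)) {
    message(sum(!out$evaluable),
            " gene(s) lack fitness data and are flagged not evaluable")
  }
  out$candidate <- out$pass_expression & out$pass_fitness
  out <- out[order(out$gene_id), , drop = FALSE]
  rownames(out) <- NULL
  list(candidates = out[out$candidate, , drop = FALSE], extended = out)
}

#' Export the quadrant scatter (relative expression vs relative fitness)
#'
#' One row per gene with both data types: the log2 ratio of target over
#' reference mean FPKM (pseudocount 1 keeps it finite), the relative
#' fitness score and T-statistic, and the per-arm pass flags under the
#' given thresholds.
#'
#' @param expr An [expression_table()] result.
#' @param gf_target,gf_reference [gene_fitness()] tables of the two plotted
#'   conditions.
#' @param target,reference The two condition names.
#' @param thresholds A [filter_thresholds()].
#' @return data.frame `gene_id`, `dlog2_expression`, `rel_score`, `rel_t`,
#'   `pass_expression`, `pass_fitness`.
#' @export
scatter_export <- function(expr, gf_target, gf_reference, target, reference,
                           thresholds = filter_thresholds()) {
  stopifnot(target %in% colnames(expr$means),
            reference %in% colnames(expr$means))
  rel <- relative_fitness(gf_target, gf_reference)
  genes <- intersect(expr$genes$gene_id, rel$gene_id)
  idx_e <- match(genes, expr$genes$gene_id)
  idx_r <- match(genes, rel$gene_id)
  ft <- expr$means[genes, target]
  fr <- expr$means[genes, reference]
  data.frame(
    gene_id = genes,
    dlog2_expression = log2((ft + 1) / (fr + 1)),
    rel_score = rel$rel_score[idx_r],
    rel_t = rel$rel_t[idx_r],
    pass_expression = expression_pass(ft, fr, q = expr$genes$q[idx_e],
                                      thresholds = thresholds),
    pass_fitness = rel$rel_score[idx_r] < thresholds$max_rel_fitness &
      rel$rel_t[idx_r] < thresholds$max_rel_t,
    stringsAsFactors = FALSE)
}
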