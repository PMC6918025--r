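# Insertion pools, gene annotations, and the barcode -> gene assignment rule.
#
# Conventions used throughout the package:
#   * genomic coordinates are 1-based, inclusive at both ends;
#   * a gene annotation is a data.frame with columns
#       gene_id, scaffold, start, end, strand, length_nt, description;
#   * an insertion pool is a data.frame with columns
#       barcode, scaffold, position, strand, assigned_genes
#     plus a "genome_name" attribute; assigned_genes is a semicolon-joined
#     string of gene ids (possibly "").

BARCODE_ALPHABET <- c("A", "C", "G", "T")

#' Read a gene annotation table
#'
#' Reads gene-level annotation from either a tab-separated table or a GFF3
#' file into the package's annotation data.frame. Coordinates are kept
#' 1-based inclusive. The `length_nt` column is the transcript length used
#' for FPKM; for GFF3 input, where no transcript length attribute is
#' available, the genomic span `end - start + 1` is used.
#'
#' @param path Path to the annotation file.
#' @param format `"tsv"` (columns gene_id, scaffold, start, end, strand,
#'   length_nt, description) or `"gff3"` (gene-level features; gene ids taken
#'   from the `ID` attribute).
#' @return A data.frame with one row per gene and columns `gene_id`,
#'   `scaffold`, `start`, `end`, `strand`, `length_nt`, `description`.
#' @export
read_gene_annotation <- function(path, format = c("tsv", "gff3")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("annotation file not found: ", path)
  genes <- switch(format,
    tsv = read_gene_annotation_tsv(path),
    gff3 = read_gene_annotation_gff3(path)
  )
  validate_gene_annotation(genes)
  genes
}

read_gene_annotation_tsv <- function(path) {
  required <- c("gene_id", "scaffold", "start", "end", "strand",
                "length_nt", "description")
  if (file.size(path) == 0) return(empty_gene_annotation())
  tab <- utils::read.delim(path, header = TRUE, sep = "\t",
                           colClasses = "character",
                           stringsAsFactors = FALSE, quote = "")
  missing_cols <- setdiff(required, names(tab))
  if (length(missing_cols) > 0) {
    stop("annotation TSV is missing column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  start <- suppressWarnings(as.integer(tab$start))
  end <- suppressWarnings(as.integer(tab$end))
  len <- suppressWarnings(as.integer(tab$length_nt))
  bad <- which(is.na(start) | is.na(end) | is.na(len) |
                 !(tab$strand %in% c("+", "-")))
  if (length(bad) > 0) {
    # +1 for the header line so the reported number matches the file
    stop("malformed annotation row at line ", bad[1] + 1L, " of ", path)
  }
  data.frame(gene_id = tab$gene_id, scaffold = tab$scaffold,
             start = start, end = end, strand = tab$strand,
             length_nt = len, description = tab$description,
             stringsAsFactors = FALSE)
}

read_gene_annotation_gff3 <- function(path) {
  gff <- as.data.frame(rtracklayer::import(path, format = "gff3"))
  gff <- gff[gff$type == "gene", , drop = FALSE]
  if (nrow(gff) == 0) return(empty_gene_annotation())
  ids <- as.character(gff$ID)
  if (anyNA(ids)) stop("GFF3 gene feature without an ID attribute in ", path)
  desc <- if ("description" %in% names(gff)) as.character(gff$description)
          else rep("", nrow(gff))
  desc[is.na(desc)] <- ""
  data.frame(gene_id = ids,
             scaffold = as.character(gff$seqnames),
             start = as.integer(gff$start),
             end = as.integer(gff$end),
             strand = as.character(gff$strand),
             length_nt = as.integer(gff$width),
             description = desc,
             stringsAsFactors = FALSE)
}

empty_gene_annotation <- function() {
  data.frame(gene_id = character(), scaffold = character(),
             start = integer(), end = integer(), strand = character(),
             length_nt = integer(), description = character(),
             stringsAsFactors = FALSE)
}

validate_gene_annotation <- function(genes) {
  if (anyDuplicated(genes$gene_id)) {
    dup <- unique(genes$gene_id[duplicated(genes$gene_id)])
    stop("duplicate gene_id in annotation: ", paste(dup, collapse = ", "))
  }
  if (any(genes$start > genes$end)) stop("gene with start > end in annotation")
  if (any(genes$length_nt < 1)) stop("gene with length_nt < 1 in annotation")
  invisible(genes)
}

#' Read an insertion-pool table
#'
#' Reads a mapped-barcode pool: one row per barcoded insertion with its
#' genomic location. Unknown extra columns are ignored.
#'
#' @param path TSV with columns `barcode`, `scaffold`, `position`, `strand`
#'   and optionally `assigned_genes` (semicolon-joined gene ids).
#' @param genome_name Optional genome label stored as an attribute.
#' @return Pool data.frame (see package conventions) with unique barcodes.
#' @export
read_pool_table <- function(path, genome_name = "unknown") {
  tab <- utils::read.delim(path, header = TRUE, sep = "\t",
                           colClasses = "character",
                           stringsAsFactors = FALSE, quote = "")
  required <- c("barcode", "scaffold", "position", "strand")
  missing_cols <- setdiff(required, names(tab))
  if (length(missing_cols) > 0) {
    stop("pool table is missing column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  assigned <- if ("assigned_genes" %in% names(tab)) tab$assigned_genes
              else rep("", nrow(tab))
  assigned[is.na(assigned)] <- ""
  pool <- data.frame(barcode = tab$barcode, scaffold = tab$scaffold,
                     position = suppressWarnings(as.integer(tab$position)),
                     strand = tab$strand, assigned_genes = assigned,
                     stringsAsFactors = FALSE)
  validate_pool(pool)
  attr(pool, "genome_name") <- genome_name
  pool
}

validate_pool <- function(pool) {
  if (anyDuplicated(pool$barcode)) {
    dup <- unique(pool$barcode[duplicated(pool$barcode)])
    stop("duplicate barcode(s) in pool: ", paste(dup, collapse = ", "))
  }
  bad <- grepl("[^ACGT]", pool$barcode)
  if (any(bad)) {
    stop("non-ACGT barcode(s) in pool: ",
         paste(pool$barcode[bad][seq_len(min(5, sum(bad)))], collapse = ", "))
  }
  if (anyNA(pool$position) || any(pool$position < 1)) {
    stop("pool contains a missing or non-positive position")
  }
  invisible(pool)
}

#' Write an insertion-pool table
#'
#' @param pool Pool data.frame.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_pool_table <- function(pool, path) {
  cols <- c("barcode", "scaffold", "position", "strand", "assigned_genes")
  if (!"assigned_genes" %in% names(pool)) pool$assigned_genes <- ""
  utils::write.table(pool[, cols], path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Assign pool insertions to genes by position containment
#'
#' An insertion is assigned to every gene whose full `[start, end]` span
#' contains its position on the same scaffold. Strand is ignored: a T-DNA
#' insertion disrupts the locus regardless of orientation. Optionally the
#' containment window can be shrunk to a central fraction of each gene
#' (insertions in the outer flanks are then left unassigned).
#'
#' @param pool Pool data.frame.
#' @param genes Gene annotation data.frame.
#' @param central_fraction Fraction in (0, 1] of each gene span, centered on
#'   its midpoint, that accepts insertions. Default 1 (the whole span).
#' @return The pool with its `assigned_genes` column recomputed
#'   (semicolon-joined gene ids, `""` for intergenic insertions).
#' @export
assign_insertions <- function(pool, genes, central_fraction = 1) {
  stopifnot(central_fraction > 0, central_fraction <= 1)
  lo <- genes$start
  hi <- genes$end
  if (central_fraction < 1) {
    mid <- (genes$start + genes$end) / 2
    half <- (genes$end - genes$start + 1) * central_fraction / 2
    lo <- ceiling(mid - half)
    hi <- floor(mid + half)
  }
  assigned <- vapply(seq_len(nrow(pool)), function(i) {
    hit <- genes$scaffold == pool$scaffold[i] &
      lo <= pool$position[i] & pool$position[i] <= hi
    paste(sort(genes$gene_id[hit]), collapse = ";")
  }, character(1))
  pool$assigned_genes <- assigned
  pool
}

#' Expand the pool's assigned_genes column to a barcode/gene map
#'
#' Barcodes assigned to several (overlapping) genes yield one row per gene;
#' unassigned barcodes are dropped.
#'
#' @param pool Pool data.frame with `assigned_genes` filled in.
#' @return data.frame with columns `barcode`, `gene_id`.
#' @export
pool_gene_map <- function(pool) {
  keep <- !is.na(pool$assigned_genes) & pool$assigned_genes != ""
  if (!any(keep)) {
    return(data.frame(barcode = character(), gene_id = character(),
                      stringsAsFactors = FALSE))
  }
  genes <- strsplit(pool$assigned_genes[keep], ";", fixed = TRUE)
  data.frame(barcode = rep(pool$barcode[keep], lengths(genes)),
             gene_id = unlist(genes, use.names = FALSE),
             stringsAsFactors = FALSE)
}
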