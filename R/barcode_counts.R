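# Extraction of flanked barcodes from reads and barcode x sample counting.

#' Flank configuration for barcode extraction
#'
#' Describes the amplicon architecture: the constant sequences immediately
#' 5' and 3' of the barcode, the barcode length, and how many mismatches the
#' flank match tolerates (the barcode itself is always matched exactly
#' against the pool). The default flanks are synthetic.
#'
#' @param pre_flank Constant sequence 5' of the barcode.
#' @param post_flank Constant sequence 3' of the barcode.
#' @param barcode_length Barcode length in nt (default 20).
#' @param max_flank_mismatches Mismatches tolerated in each flank (default 0).
#' @return A list of class `"flank_config"`.
#' @export
flank_config <- function(pre_flank = "GATGTCCACGAGGTCTCT",
                         post_flank = "CGTACGCTGCAGGTCGAC",
                         barcode_length = 20,
                         max_flank_mismatches = 0) {
  stopifnot(nchar(pre_flank) > 0, nchar(post_flank) > 0,
            barcode_length >= 1, max_flank_mismatches >= 0)
  structure(list(pre_flank = toupper(pre_flank),
                 post_flank = toupper(post_flank),
                 barcode_length = as.integer(barcode_length),
                 max_flank_mismatches = as.integer(max_flank_mismatches)),
            class = "flank_config")
}

hamming_le <- function(strings, pattern, max_mm) {
  # TRUE where each string (same length as pattern) is within max_mm
  # mismatches of pattern; FALSE for length mismatches.
  n <- nchar(pattern)
  ok <- !is.na(strings) & nchar(strings) == n
  if (!any(ok)) return(ok)
  if (max_mm == 0) {
    ok[ok] <- strings[ok] == pattern
    return(ok)
  }
  pr <- charToRaw(pattern)
  mm <- vapply(strings[ok], function(s) sum(charToRaw(s) != pr), integer(1),
               USE.NAMES = FALSE)
  ok[ok] <- mm <= max_mm
  ok
}

#' Extract flanked barcodes from reads
#'
#' For each read, finds the first occurrence of the 5' flank (within the
#' configured mismatch tolerance), takes the following
#' `barcode_length`-mer as the barcode, and keeps it only if the 3' flank
#' follows, also within tolerance. Absence is reported as `NA`, not an
#' error.
#'
#' @param reads Character vector of read sequences.
#' @param flanks A [flank_config()].
#' @return Character vector of barcodes, `NA` where no valid barcode was
#'   found.
#' @export
extract_barcode <- function(reads, flanks) {
  stopifnot(inherits(flanks, "flank_config"))
  reads <- toupper(reads)
  n_pre <- nchar(flanks$pre_flank)
  bl <- flanks$barcode_length
  mm <- flanks$max_flank_mismatches
  if (mm == 0) {
    start <- regexpr(flanks$pre_flank, reads, fixed = TRUE)
    start <- ifelse(start < 0, NA_integer_, as.integer(start))
  } else {
    hits <- Biostrings::vmatchPattern(flanks$pre_flank,
                                      Biostrings::DNAStringSet(reads),
                                      max.mismatch = mm)
    start <- vapply(Biostrings::startIndex(hits), function(s) {
      if (is.null(s) || length(s) == 0) NA_integer_ else s[1]
    }, integer(1))
  }
  bc_start <- start + n_pre
  barcode <- substr(reads, bc_start, bc_start + bl - 1L)
  post_obs <- substr(reads, bc_start + bl,
                     bc_start + bl + nchar(flanks$post_flank) - 1L)
  ok <- !is.na(start) & nchar(barcode) == bl &
    !grepl("[^ACGT]", barcode) &
    hamming_le(post_obs, flanks$post_flank, mm)
  ifelse(ok, barcode, NA_character_)
}

read_fastq_sequences <- function(path) {
  # file() auto-detects gz; an empty (or empty-after-decompression) FASTQ
  # is a valid sample with zero reads
  if (length(readLines(path, n = 1)) == 0) return(character(0))
  as.character(Biostrings::readDNAStringSet(path, format = "fastq"))
}

#' Count pool barcodes in FASTQ samples
#'
#' Extracts barcodes from each FASTQ file and counts exact matches against
#' the pool. Extracted barcodes absent from the pool accumulate per sample
#' in the `unmapped` attribute; reads without an extractable barcode in the
#' `unextractable` attribute, so per sample
#' `colSums(counts) + unmapped + unextractable == reads`.
#'
#' @param fastq_paths Character vector of FASTQ paths (gz transparent); one
#'   sample per file. Names, if set, become sample labels (default:
#'   file base names).
#' @param pool Pool data.frame (non-empty).
#' @param flanks A [flank_config()].
#' @param reverse_complement Also scan the reverse complement of each read
#'   when the forward orientation yields no barcode. Default `FALSE`.
#' @return Integer matrix barcodes x samples with attributes `unmapped`,
#'   `unextractable` and `total_reads` (named per-sample integer vectors).
#' @export
count_barcodes <- function(fastq_paths, pool, flanks,
                           reverse_complement = FALSE) {
  stopifnot(nrow(pool) > 0, inherits(flanks, "flank_config"))
  labels <- names(fastq_paths)
  if (is.null(labels)) {
    labels <- sub("\\.(fastq|fq)(\\.gz)?$", "", basename(fastq_paths))
  }
  counts <- matrix(0L, nrow = nrow(pool), ncol = length(fastq_paths),
                   dimnames = list(pool$barcode, labels))
  unmapped <- stats::setNames(integer(length(fastq_paths)), labels)
  unextract <- stats::setNames(integer(length(fastq_paths)), labels)
  total <- stats::setNames(integer(length(fastq_paths)), labels)
  for (s in seq_along(fastq_paths)) {
    if (!file.exists(fastq_paths[s])) {
      stop("FASTQ not found: ", fastq_paths[s])
    }
    reads <- read_fastq_sequences(fastq_paths[s])
    total[s] <- length(reads)
    bc <- extract_barcode(reads, flanks)
    if (reverse_complement && anyNA(bc)) {
      miss <- is.na(bc)
      rc <- as.character(Biostrings::reverseComplement(
        Biostrings::DNAStringSet(reads[miss])))
      bc[miss] <- extract_barcode(rc, flanks)
    }
    unextract[s] <- sum(is.na(bc))
    bc <- bc[!is.na(bc)]
    hit <- bc %in% pool$barcode
    unmapped[s] <- sum(!hit)
    tab <- table(factor(bc[hit], levels = pool$barcode))
    counts[, s] <- as.integer(tab)
  }
  attr(counts, "unmapped") <- unmapped
  attr(counts, "unextractable") <- unextract
  attr(counts, "total_reads") <- total
  counts
}

#' Write / read a count matrix as TSV
#'
#' Rows are barcodes (or genes), columns samples; row ids go in a leading
#' `id` column. The writer appends `unmapped` and `unextractable` rows when
#' the matrix carries those attributes; the reader strips them back into
#' attributes.
#'
#' @param counts Integer matrix with dimnames.
#' @param path TSV path.
#' @return `path` invisibly (writer); the matrix (reader).
#' @export
write_count_matrix <- function(counts, path) {
  out <- data.frame(id = rownames(counts), counts, check.names = FALSE,
                    stringsAsFactors = FALSE)
  for (extra in c("unmapped", "unextractable")) {
    v <- attr(counts, extra)
    if (!is.null(v)) {
      out <- rbind(out, data.frame(id = paste0("_", extra), t(v),
                                   check.names = FALSE))
    }
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_count_matrix
#' @export
read_count_matrix <- function(path) {
  tab <- utils::read.delim(path, header = TRUE, sep = "\t",
                           check.names = FALSE, stringsAsFactors = FALSE)
  extras <- grepl("^_", tab$id)
  m <- as.matrix(tab[!extras, -1, drop = FALSE])
  rownames(m) <- tab$id[!extras]
  storage.mode(m) <- "integer"
  for (extra in c("unmapped", "unextractable")) {
    row <- which(tab$id == paste0("_", extra))
    if (length(row) == 1) {
      v <- as.integer(tab[row, -1])
      names(v) <- colnames(m)
      attr(m, extra) <- v
    }
  }
  m
}
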