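#' Count matrix with sample and gene annotation
#'
#' The central expression container: an integer gene x sample count matrix
#' plus a sample sheet (condition, timepoint, batch) and a gene sheet
#' (chrom, TSS, strand, length). Modeled on the light list-based containers
#' of edgeR/limma rather than S4. All genomic coordinates are 0-based
#' half-open; the TSS is a single 0-based position.
#'
#' @param counts integer matrix, genes x samples, with dimnames.
#' @param samples data.frame with columns `id`, `condition` ("injury"/"sham"),
#'   `timepoint` ("day1"/"day14"), `batch`.
#' @param genes data.frame with columns `id`, `chrom`, `tss` (0-based),
#'   `strand` ("+"/"-"), `length` (bp, >= 1).
#' @return object of class `CountMatrix`.
#' @export
CountMatrix <- function(counts, samples, genes) {
  counts <- as.matrix(counts)
  obj <- structure(list(counts = counts, samples = samples, genes = genes),
                   class = "CountMatrix")
  validate_count_matrix(obj)
}

validate_count_matrix <- function(x) {
  counts <- x$counts; samples <- x$samples; genes <- x$genes
  need_s <- c("id", "condition", "timepoint", "batch")
  need_g <- c("id", "chrom", "tss", "strand", "length")
  if (!all(need_s %in% names(samples)))
    stop_located("sample sheet missing column(s): %s",
                 paste(setdiff(need_s, names(samples)), collapse = ", "))
  if (!all(need_g %in% names(genes)))
    stop_located("gene sheet missing column(s): %s",
                 paste(setdiff(need_g, names(genes)), collapse = ", "))
  if (nrow(counts) != nrow(genes))
    stop_located("counts has %d rows but gene sheet has %d", nrow(counts), nrow(genes))
  if (ncol(counts) != nrow(samples))
    stop_located("counts has %d columns but sample sheet has %d", ncol(counts), nrow(samples))
  if (anyDuplicated(genes$id))
    stop_located("duplicate gene id(s): %s",
                 paste(unique(genes$id[duplicated(genes$id)]), collapse = ", "))
  if (anyDuplicated(samples$id))
    stop_located("duplicate sample id(s): %s",
                 paste(unique(samples$id[duplicated(samples$id)]), collapse = ", "))
  bad <- which(!(counts >= 0 & counts == round(counts)), arr.ind = TRUE)
  if (nrow(bad)) {
    stop_located("non-integer or negative count at gene '%s', sample '%s' (value %s)",
                 genes$id[bad[1, 1]], samples$id[bad[1, 2]],
                 format(counts[bad[1, , drop = FALSE]]))
  }
  if (!all(samples$condition %in% c("injury", "sham")))
    stop_located("condition must be 'injury' or 'sham'; got: %s",
                 paste(setdiff(unique(samples$condition), c("injury", "sham")), collapse = ", "))
  if (!all(samples$timepoint %in% c("day1", "day14")))
    stop_located("timepoint must be 'day1' or 'day14'; got: %s",
                 paste(setdiff(unique(samples$timepoint), c("day1", "day14")), collapse = ", "))
  if (!all(genes$strand %in% c("+", "-")))
    stop_located("strand must be '+' or '-'")
  if (any(genes$length < 1)) stop_located("gene length must be >= 1 bp")
  rownames(x$counts) <- genes$id
  colnames(x$counts) <- samples$id
  x
}

#' @export
print.CountMatrix <- function(x, ...) {
  cat(sprintf("CountMatrix: %d genes x %d samples\n", nrow(x$counts), ncol(x$counts)))
  tab <- table(x$samples$condition, x$samples$timepoint)
  print(tab)
  invisible(x)
}

#' @export
dim.CountMatrix <- function(x) dim(x$counts)

#' Read a count matrix, sample sheet and gene sheet from TSV files
#'
#' The counts file follows the featureCounts-style export dialect: genes as
#' rows, samples as columns, first column the gene id. Column order of the
#' returned counts matches the sample-sheet order. Validation is strict:
#' missing samples and non-integer counts are hard errors naming the
#' offending entry.
#'
#' @param path_counts TSV of counts (first column gene id).
#' @param path_samples TSV with columns id, condition, timepoint, batch.
#' @param path_genes TSV with columns id, chrom, tss, strand, length.
#' @return a [CountMatrix].
#' @export
read_count_matrix <- function(path_counts, path_samples, path_genes) {
  for (p in c(path_counts, path_samples, path_genes))
    if (!file.exists(p)) stop_located("file not found: %s", p)
  raw <- read.delim(path_counts, check.names = FALSE, comment.char = "#",
                    stringsAsFactors = FALSE)
  samples <- read.delim(path_samples, comment.char = "#", stringsAsFactors = FALSE)
  genes <- read.delim(path_genes, comment.char = "#", stringsAsFactors = FALSE)
  gene_ids <- as.character(raw[[1]])
  mat <- raw[, -1, drop = FALSE]
  missing <- setdiff(colnames(mat), samples$id)
  if (length(missing))
    stop_located("sample(s) present in counts but absent from metadata: %s",
                 paste(missing, collapse = ", "))
  absent <- setdiff(samples$id, colnames(mat))
  if (length(absent))
    stop_located("sample(s) in metadata but absent from counts: %s",
                 paste(absent, collapse = ", "))
  for (j in seq_along(mat)) {
    v <- suppressWarnings(as.numeric(mat[[j]]))
    bad <- which(is.na(v) | v < 0 | v != round(v))
    if (length(bad))
      stop_located("non-integer count at gene '%s', sample '%s' (value '%s')",
                   gene_ids[bad[1]], colnames(mat)[j], as.character(mat[[j]][bad[1]]))
  }
  counts <- as.matrix(mat)[, samples$id, drop = FALSE]
  storage.mode(counts) <- "numeric"
  rownames(counts) <- gene_ids
  if (!identical(sort(gene_ids), sort(as.character(genes$id))))
    stop_located("gene ids in counts and gene sheet differ")
  genes <- genes[match(gene_ids, genes$id), , drop = FALSE]
  rownames(genes) <- NULL
  CountMatrix(counts, samples, genes)
}

#' Write a CountMatrix back to its three-TSV on-disk form
#'
#' Inverse of [read_count_matrix()]; `read_count_matrix(write_count_matrix(x))`
#' round-trips byte-identically for integer counts.
#'
#' @param cm a [CountMatrix].
#' @param dir output directory (created if needed).
#' @param prefix file-name prefix.
#' @return named character vector of the three paths, invisibly.
#' @export
write_count_matrix <- function(cm, dir, prefix = "expr") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(counts = file.path(dir, paste0(prefix, "_counts.tsv")),
             samples = file.path(dir, paste0(prefix, "_samples.tsv")),
             genes = file.path(dir, paste0(prefix, "_genes.tsv")))
  ctab <- data.frame(gene = rownames(cm$counts), cm$counts, check.names = FALSE)
  write.table(ctab, paths["counts"], sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(cm$samples, paths["samples"], sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(cm$genes, paths["genes"], sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(paths)
}

#' Convert 1-based closed gene records (GTF convention) to internal 0-based TSS
#'
#' Internally every coordinate is 0-based half-open (BED/bedGraph convention).
#' GTF gene records are 1-based closed; the TSS of a `+` gene is `start - 1`
#' and of a `-` gene is `end - 1` in 0-based coordinates.
#'
#' @param start,end 1-based closed gene span.
#' @param strand "+" or "-".
#' @return integer 0-based TSS position.
#' @export
tss_from_gtf <- function(start, end, strand) {
  stopifnot(all(strand %in% c("+", "-")), all(end >= start), all(start >= 1))
  as.integer(ifelse(strand == "+", start - 1, end - 1))
}
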