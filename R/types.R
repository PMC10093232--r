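#' eccdiff: differential analysis of genic extrachromosomal circular DNA
#'
#' Core containers are lightweight S3 objects wrapping data frames:
#' `circle_catalog` (one sample's circle calls), `gene_annotation`
#' (gene intervals), `ppgc_matrix` (genes x samples quantification) and
#' `dppgc` (differential results). All genomic coordinates follow the BED
#' convention: 0-based, half-open, so `length = end - start`.
#'
#' @keywords internal
"_PACKAGE"

#' Construct a circle catalog
#'
#' A circle catalog holds the eccDNA calls of one sample: genomic interval
#' plus the number of split (junction-spanning) reads supporting the
#' back-junction. Calls are sorted by (chrom, start, end); exact duplicate
#' intervals are not collapsed here (see [read_circle_table()] for the
#' read-time collapse rule).
#'
#' @param calls data.frame with columns `chrom`, `start`, `end`,
#'   `split_reads`. Coordinates are 0-based half-open.
#' @param sample_id sample identifier.
#' @param group group label (e.g. `"HC"` or `"SLE"`).
#' @return A `circle_catalog`: the validated, sorted data.frame with
#'   attributes `sample_id` and `group` and a derived `length` column.
#' @export
circle_catalog <- function(calls, sample_id, group) {
  stopifnot(is.data.frame(calls))
  required <- c("chrom", "start", "end", "split_reads")
  missing_cols <- setdiff(required, names(calls))
  if (length(missing_cols) > 0L) {
    stop("circle catalog is missing columns: ", paste(missing_cols, collapse = ", "))
  }
  calls <- calls[required]
  calls$chrom <- as.character(calls$chrom)
  calls$start <- as.numeric(calls$start)
  calls$end <- as.numeric(calls$end)
  calls$split_reads <- as.numeric(calls$split_reads)
  if (nrow(calls) > 0L) {
    if (any(!is.finite(calls$start)) || any(!is.finite(calls$end))) {
      stop("non-finite coordinates in circle catalog")
    }
    if (any(calls$start < 0) || any(calls$start >= calls$end)) {
      stop("invalid interval: need 0 <= start < end")
    }
    if (any(calls$split_reads < 0)) stop("split_reads must be non-negative")
  }
  calls <- calls[order(calls$chrom, calls$start, calls$end), , drop = FALSE]
  rownames(calls) <- NULL
  calls$length <- calls$end - calls$start
  structure(calls,
    sample_id = as.character(sample_id),
    group = as.character(group),
    class = c("circle_catalog", "data.frame")
  )
}

#' @export
print.circle_catalog <- function(x, ...) {
  cat(sprintf(
    "circle_catalog: sample %s (group %s), %d calls, %s split reads\n",
    attr(x, "sample_id"), attr(x, "group"), nrow(x),
    format(sum(x$split_reads), big.mark = ",")
  ))
  if (nrow(x) > 0L) print(utils::head(as.data.frame(x), 6L))
  invisible(x)
}

#' Sample id of a circle catalog
#' @param x a `circle_catalog`.
#' @return character scalar.
#' @export
sample_id <- function(x) attr(x, "sample_id")

#' Group label of a circle catalog
#' @param x a `circle_catalog`.
#' @return character scalar.
#' @export
group_label <- function(x) attr(x, "group")

# rebuild a catalog from a subset of rows, preserving labels
catalog_like <- function(template, rows) {
  circle_catalog(
    as.data.frame(rows)[c("chrom", "start", "end", "split_reads")],
    sample_id = attr(template, "sample_id"),
    group = attr(template, "group")
  )
}

#' Construct a gene annotation
#'
#' @param genes data.frame with columns `chrom`, `start`, `end`, `name`
#'   (BED4 semantics, 0-based half-open). Gene symbols are stored
#'   upper-case; duplicated symbols are disambiguated with `#k` suffixes in
#'   input order (`GENE_A#1`, `GENE_A#2`, ...), since gene-keyed matrices
#'   need unique keys.
#' @return A `gene_annotation` data.frame with a derived `length` column.
#' @export
gene_annotation <- function(genes) {
  stopifnot(is.data.frame(genes))
  required <- c("chrom", "start", "end", "name")
  missing_cols <- setdiff(required, names(genes))
  if (length(missing_cols) > 0L) {
    stop("gene annotation is missing columns: ", paste(missing_cols, collapse = ", "))
  }
  genes <- genes[required]
  if (nrow(genes) == 0L) stop("no genes in annotation")
  genes$chrom <- as.character(genes$chrom)
  genes$start <- as.numeric(genes$start)
  genes$end <- as.numeric(genes$end)
  genes$name <- toupper(as.character(genes$name))
  if (any(is.na(genes$name)) || any(!nzchar(genes$name))) {
    stop("gene names must be non-empty")
  }
  if (any(genes$start < 0) || any(genes$start >= genes$end)) {
    stop("invalid gene interval: need 0 <= start < end (zero-length genes rejected)")
  }
  dup <- names(which(table(genes$name) > 1L))
  if (length(dup) > 0L) {
    for (nm in dup) {
      idx <- which(genes$name == nm)
      genes$name[idx] <- paste0(nm, "#", seq_along(idx))
    }
  }
  genes$length <- genes$end - genes$start
  genes <- genes[order(genes$chrom, genes$start, genes$end), , drop = FALSE]
  rownames(genes) <- NULL
  structure(genes, class = c("gene_annotation", "data.frame"))
}

#' @export
print.gene_annotation <- function(x, ...) {
  cat(sprintf(
    "gene_annotation: %d genes on %d chromosomes, lengths %d-%d bp\n",
    nrow(x), length(unique(x$chrom)), min(x$length), max(x$length)
  ))
  print(utils::head(as.data.frame(x), 6L))
  invisible(x)
}

# 1-based closed GRanges view of 0-based half-open intervals
as_granges0 <- function(df) {
  GenomicRanges::GRanges(
    seqnames = df$chrom,
    ranges = IRanges::IRanges(start = df$start + 1L, end = df$end)
  )
}
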