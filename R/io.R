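#' Read a per-sample circle call table
#'
#' Parses the tab-separated output of a split-read circle caller: columns
#' `chrom`, `start`, `end`, `split_reads` (extra columns ignored). Lines
#' starting with `#` are treated as comments/headers. Exact duplicate
#' intervals within a sample are collapsed by summing their split reads, so
#' the catalog enumerates unique eccDNA.
#'
#' @param path path to the TSV file.
#' @param sample_id sample identifier to attach.
#' @param group group label to attach.
#' @return a [circle_catalog()].
#' @export
read_circle_table <- function(path, sample_id, group) {
  if (!file.exists(path)) stop("circle table not found: ", path)
  lines <- readLines(path)
  keep <- !startsWith(trimws(lines), "#") & nzchar(trimws(lines))
  if (!any(keep)) {
    warning("empty circle table: ", path)
    return(circle_catalog(
      data.frame(chrom = character(), start = numeric(), end = numeric(),
                 split_reads = numeric()),
      sample_id = sample_id, group = group
    ))
  }
  lineno <- which(keep)
  fields <- strsplit(lines[keep], "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 4L)) {
    stop(sprintf("line %d of %s: expected >= 4 tab-separated fields",
                 lineno[which(nf < 4L)[1L]], path))
  }
  chrom <- vapply(fields, `[[`, "", 1L)
  start <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 2L)))
  end <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 3L)))
  sr <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 4L)))
  bad <- which(is.na(start) | is.na(end) | is.na(sr) |
                 start != floor(start) | end != floor(end) | sr != floor(sr))
  if (length(bad) > 0L) {
    stop(sprintf("line %d of %s: non-integer coordinates or split-read count",
                 lineno[bad[1L]], path))
  }
  bad <- which(start < 0 | start >= end)
  if (length(bad) > 0L) {
    stop(sprintf("line %d of %s: invalid interval (need 0 <= start < end)",
                 lineno[bad[1L]], path))
  }
  bad <- which(sr < 0)
  if (length(bad) > 0L) {
    stop(sprintf("line %d of %s: negative split-read count", lineno[bad[1L]], path))
  }
  df <- data.frame(chrom = chrom, start = start, end = end, split_reads = sr,
                   stringsAsFactors = FALSE)
  df <- stats::aggregate(split_reads ~ chrom + start + end, data = df, FUN = sum)
  circle_catalog(df, sample_id = sample_id, group = group)
}

#' Read a BED4 gene annotation
#'
#' @param path path to a BED file with at least 4 columns: chrom, start,
#'   end, gene name (0-based half-open).
#' @return a [gene_annotation()].
#' @export
read_gene_bed <- function(path) {
  if (!file.exists(path)) stop("gene BED not found: ", path)
  df <- tryCatch(
    utils::read.table(path, sep = "\t", header = FALSE, comment.char = "#",
                      stringsAsFactors = FALSE, quote = ""),
    error = function(e) stop("no genes in ", path)
  )
  if (ncol(df) < 4L) stop("gene BED needs >= 4 columns (chrom, start, end, name): ", path)
  gene_annotation(stats::setNames(df[, 1:4], c("chrom", "start", "end", "name")))
}

#' Read a GMT gene-set collection
#'
#' Standard GMT: one set per line, tab-separated `term`, `description`,
#' then member gene symbols. Members are upper-cased for case-insensitive
#' matching; lines with fewer than 3 fields are skipped with a warning.
#'
#' @param path path to the GMT file.
#' @return named list of gene sets; each element is a list with `term_id`,
#'   `term_name` and `members` (character vector).
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stop("GMT file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  short <- lengths(fields) < 3L
  if (any(short)) {
    warning(sum(short), " GMT line(s) with < 3 fields skipped")
    fields <- fields[!short]
  }
  sets <- lapply(fields, function(f) {
    list(term_id = f[[1L]], term_name = f[[2L]],
         members = unique(toupper(f[-(1:2)])))
  })
  stats::setNames(sets, vapply(sets, `[[`, "", "term_id"))
}

#' Read a sample manifest
#'
#' Tab-separated table with columns `sample_id`, `path`, `group` (a header
#' line with exactly those names is recognised and skipped). Relative
#' circle-table paths are resolved against the manifest's directory.
#'
#' @param path path to the manifest TSV.
#' @return data.frame with columns `sample_id`, `path`, `group`.
#' @export
read_manifest <- function(path) {
  if (!file.exists(path)) stop("manifest not found: ", path)
  df <- utils::read.table(path, sep = "\t", header = FALSE, comment.char = "#",
                          stringsAsFactors = FALSE, quote = "")
  if (ncol(df) < 3L) stop("manifest needs 3 columns: sample_id, path, group")
  df <- df[, 1:3]
  names(df) <- c("sample_id", "path", "group")
  if (identical(unname(tolower(unlist(df[1L, ]))), c("sample_id", "path", "group"))) {
    df <- df[-1L, , drop = FALSE]
  }
  if (anyDuplicated(df$sample_id)) stop("duplicate sample_id in manifest")
  groups <- unique(df$group)
  if (length(groups) != 2L) {
    stop("manifest must contain exactly two group labels, found: ",
         paste(groups, collapse = ", "))
  }
  rel <- !file.exists(df$path) & !grepl("^(/|[A-Za-z]:)", df$path)
  df$path[rel] <- file.path(dirname(path), df$path[rel])
  rownames(df) <- NULL
  df
}

#' Read all catalogs of a manifest
#'
#' @param manifest data.frame as returned by [read_manifest()].
#' @return named list of [circle_catalog()]s, one per sample.
#' @export
read_catalogs <- function(manifest) {
  out <- lapply(seq_len(nrow(manifest)), function(i) {
    read_circle_table(manifest$path[i], manifest$sample_id[i], manifest$group[i])
  })
  stats::setNames(out, manifest$sample_id)
}

#' Write a circle catalog as a 4-column BED-like TSV
#'
#' The `#`-prefixed header makes the file directly re-readable with
#' [read_circle_table()]; write/read round-trips preserve
#' (chrom, start, end, split_reads) exactly.
#'
#' @param catalog a [circle_catalog()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_catalog <- function(catalog, path) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines("#chrom\tstart\tend\tsplit_reads", con)
  if (nrow(catalog) > 0L) {
    writeLines(sprintf("%s\t%d\t%d\t%d", catalog$chrom,
                       as.integer(catalog$start), as.integer(catalog$end),
                       as.integer(catalog$split_reads)), con)
  }
  invisible(path)
}

# Deterministic TSV writer used for all result tables: fixed column order,
# full double precision (~15 significant digits), no quoting, no rownames.
write_tsv <- function(df, path) {
  df2 <- df
  for (j in seq_along(df2)) {
    if (is.numeric(df2[[j]])) df2[[j]] <- vapply(df2[[j]], format_num, "")
    if (is.logical(df2[[j]])) df2[[j]] <- ifelse(df2[[j]], "TRUE", "FALSE")
  }
  utils::write.table(df2, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

format_num <- function(x) {
  if (is.na(x)) return("NA")
  if (is.finite(x) && x == floor(x) && abs(x) < 1e15) return(sprintf("%.0f", x))
  format(x, digits = 15, scientific = FALSE, trim = TRUE)
}

#' Read a PpGC matrix table written by [write_results()]
#'
#' @param path path to a PpGC TSV (first column `gene`, one column per
#'   sample).
#' @return numeric matrix, genes in rows, samples in columns.
#' @export
read_ppgc_table <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE, check.names = FALSE,
                          stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1L, drop = FALSE])
  rownames(m) <- df[[1L]]
  m
}

#' Write all pipeline result tables
#'
#' Writes whichever components are present in `results` (the object
#' returned by [run_pipeline()] or an equivalently named list):
#' filtered/merged catalogs, raw/scaled/equalized PpGC tables, the DPpGC
#' table (ordered by ascending p, then descending |diff|, then gene), the
#' whole-gene report, length statistics and enrichment tables. Row order of
#' every file is a deterministic function of the content.
#'
#' @param results named list of result components.
#' @param outdir output directory (created if needed).
#' @return character vector of files written, invisibly.
#' @export
write_results <- function(results, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(outdir)) stop("cannot create output directory: ", outdir)
  written <- character()
  put <- function(df, name) {
    p <- file.path(outdir, name)
    write_tsv(df, p)
    written <<- c(written, p)
  }
  if (!is.null(results$catalogs)) {
    cdir <- file.path(outdir, "catalogs")
    dir.create(cdir, showWarnings = FALSE)
    for (cat_i in results$catalogs) {
      p <- file.path(cdir, paste0(sample_id(cat_i), ".circles.tsv"))
      write_catalog(cat_i, p)
      written <- c(written, p)
    }
  }
  if (!is.null(results$ppgc)) {
    m <- results$ppgc
    for (layer in c("raw", "scaled", "equalized")) {
      df <- data.frame(gene = rownames(m[[layer]]), m[[layer]],
                       check.names = FALSE, stringsAsFactors = FALSE)
      put(df, sprintf("ppgc_%s.tsv", layer))
    }
  }
  if (!is.null(results$dppgc)) put(as.data.frame(results$dppgc), "dppgc.tsv")
  if (!is.null(results$whole_genes)) {
    put(results$whole_genes$recurrent, "whole_genes_recurrent.tsv")
    per <- results$whole_genes$per_sample
    df <- data.frame(
      sample_id = rep(names(per), lengths(per)),
      gene = unlist(per, use.names = FALSE),
      stringsAsFactors = FALSE
    )
    if (nrow(df) == 0L) df <- data.frame(sample_id = character(), gene = character())
    put(df[order(df$sample_id, df$gene), , drop = FALSE], "whole_genes_per_sample.tsv")
  }
  if (!is.null(results$counts)) put(results$counts, "sample_counts.tsv")
  if (!is.null(results$count_comparison)) {
    put(as.data.frame(results$count_comparison), "group_count_comparison.tsv")
  }
  if (!is.null(results$length_summary)) {
    ls <- results$length_summary
    put(ls$density, "length_density.tsv")
    put(ls$peaks, "length_peaks.tsv")
    put(ls$cdf, "length_cdf.tsv")
    put(ls$rhomboid, "rhomboid_vertices.tsv")
  }
  if (!is.null(results$enrichment)) put(results$enrichment, "enrichment.tsv")
  if (!is.null(results$run_manifest)) {
    p <- file.path(outdir, "run_manifest.json")
    jsonlite::write_json(results$run_manifest, p, auto_unbox = TRUE,
                         pretty = TRUE, digits = NA)
    written <- c(written, p)
  }
  invisible(written)
}
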