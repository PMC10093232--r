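#' Assign overlapping genes to circles
#'
#' Half-open interval intersection (bedtools-intersect semantics, strand
#' ignored): a circle is assigned every gene it overlaps by at least 1 bp.
#' Abutting half-open intervals (circle start == gene end) do not overlap.
#'
#' @param catalog a filtered, merged [circle_catalog()].
#' @param genes a [gene_annotation()].
#' @return data.frame with one row per (circle, gene) overlap: `circle`
#'   (row index into `catalog`), `gene`, `gene_length`, `split_reads`,
#'   `circle_length`, `overlap_bp`. Attribute `n_unassigned` counts circles
#'   overlapping no gene. Chromosomes present in the catalog but absent
#'   from the annotation are reported once via [message()].
#' @export
annotate_circles <- function(catalog, genes) {
  missing_chr <- setdiff(unique(catalog$chrom), unique(genes$chrom))
  if (length(missing_chr) > 0L) {
    message("chromosomes absent from annotation (no assignments): ",
            paste(sort(missing_chr), collapse = ", "))
  }
  empty <- data.frame(circle = integer(), gene = character(),
                      gene_length = numeric(), split_reads = numeric(),
                      circle_length = numeric(), overlap_bp = numeric(),
                      stringsAsFactors = FALSE)
  if (nrow(catalog) == 0L) {
    attr(empty, "n_unassigned") <- 0L
    attr(empty, "sample_id") <- sample_id(catalog)
    return(empty)
  }
  hits <- suppressWarnings(GenomicRanges::findOverlaps(
    as_granges0(catalog), as_granges0(genes), minoverlap = 1L
  ))
  q <- S4Vectors::queryHits(hits)
  s <- S4Vectors::subjectHits(hits)
  out <- if (length(q) == 0L) empty else data.frame(
    circle = q,
    gene = genes$name[s],
    gene_length = genes$length[s],
    split_reads = catalog$split_reads[q],
    circle_length = catalog$length[q],
    overlap_bp = pmin(catalog$end[q], genes$end[s]) -
      pmax(catalog$start[q], genes$start[s]),
    stringsAsFactors = FALSE
  )
  out <- out[order(out$circle, out$gene), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_unassigned") <- nrow(catalog) - length(unique(q))
  attr(out, "sample_id") <- sample_id(catalog)
  out
}

#' Compute the produced-per-gene circles (PpGC) matrix
#'
#' For each gene and sample, the split reads of every circle overlapping
#' the gene (whole gene or fragment) are summed into the unscaled PpGC. A
#' circle overlapping k genes contributes its full split-read count to each
#' of them by default (`attribution = "full"`); `"proportional"` instead
#' apportions by overlap length / circle length. Unscaled counts are then
#' scaled by L_Max / L_i, where L_i is the gene length and L_Max the length
#' of the longest gene detected in the run (not the longest in the whole
#' annotation), and finally equalized as log2(scaled + 1). Genes with zero
#' counts in every sample are dropped.
#'
#' @param assignments named list (one element per sample, names are sample
#'   ids) of [annotate_circles()] outputs.
#' @param manifest data.frame with columns `sample_id`, `group` covering
#'   every element of `assignments`.
#' @param attribution `"full"` or `"proportional"` multi-gene attribution.
#' @return a `ppgc_matrix`: list with matrices `raw`, `scaled`,
#'   `equalized` (genes x samples), `samples` (data.frame sample_id,
#'   group), `gene_lengths` (named vector) and `l_max` (bp).
#' @export
compute_ppgc <- function(assignments, manifest,
                         attribution = c("full", "proportional")) {
  attribution <- match.arg(attribution)
  missing_s <- setdiff(manifest$sample_id, names(assignments))
  if (length(missing_s) > 0L) {
    stop("assignments missing for samples: ", paste(missing_s, collapse = ", "))
  }
  samples <- manifest$sample_id
  long <- do.call(rbind, lapply(samples, function(s) {
    a <- assignments[[s]]
    if (nrow(a) == 0L) return(NULL)
    w <- if (attribution == "full") a$split_reads else
      a$split_reads * a$overlap_bp / a$circle_length
    data.frame(sample = s, gene = a$gene, gene_length = a$gene_length,
               weight = w, stringsAsFactors = FALSE)
  }))
  if (is.null(long) || nrow(long) == 0L) stop("no genic eccDNA in any sample")
  genes <- sort(unique(long$gene))
  gl <- long$gene_length[match(genes, long$gene)]
  names(gl) <- genes
  raw <- matrix(0, nrow = length(genes), ncol = length(samples),
                dimnames = list(genes, samples))
  agg <- stats::aggregate(weight ~ gene + sample, data = long, FUN = sum)
  raw[cbind(agg$gene, agg$sample)] <- agg$weight
  keep <- rowSums(raw) > 0
  raw <- raw[keep, , drop = FALSE]
  gl <- gl[keep]
  if (nrow(raw) == 0L) stop("no genic eccDNA in any sample")
  l_max <- max(gl)
  scaled <- raw * (l_max / gl)
  equalized <- log2(scaled + 1)
  structure(
    list(raw = raw, scaled = scaled, equalized = equalized,
         samples = data.frame(sample_id = samples, group = manifest$group,
                              stringsAsFactors = FALSE),
         gene_lengths = gl, l_max = l_max),
    class = "ppgc_matrix"
  )
}

#' @export
print.ppgc_matrix <- function(x, ...) {
  cat(sprintf(
    "ppgc_matrix: %d genes x %d samples (groups: %s), L_Max = %d bp\n",
    nrow(x$raw), ncol(x$raw),
    paste(sprintf("%s n=%d", names(table(x$samples$group)),
                  as.integer(table(x$samples$group))), collapse = ", "),
    as.integer(x$l_max)
  ))
  invisible(x)
}

#' Whole genes carried by circles
#'
#' A gene is whole-carried in a sample when some circle's interval fully
#' contains the gene's interval. The report lists the per-sample whole
#' genes and the recurrent ones (carried in at least 2 samples) with N, the
#' number of carrying samples, and L, the gene length.
#'
#' @param catalogs named list of filtered, merged [circle_catalog()]s.
#' @param genes a [gene_annotation()].
#' @return list with `per_sample` (named list of sorted gene symbol
#'   vectors) and `recurrent` (data.frame gene, N, L, samples ordered by
#'   decreasing N then gene).
#' @export
whole_gene_carriage <- function(catalogs, genes) {
  gr_genes <- as_granges0(genes)
  per_sample <- lapply(catalogs, function(cat_i) {
    if (nrow(cat_i) == 0L) return(character())
    hits <- suppressWarnings(GenomicRanges::findOverlaps(
      gr_genes, as_granges0(cat_i), type = "within"
    ))
    sort(unique(genes$name[S4Vectors::queryHits(hits)]))
  })
  names(per_sample) <- vapply(catalogs, sample_id, "")
  tab <- table(unlist(per_sample, use.names = FALSE))
  rec_genes <- sort(as.character(names(tab)[tab >= 2L]))
  recurrent <- data.frame(
    gene = rec_genes,
    N = as.integer(tab[rec_genes]),
    L = as.integer(genes$length[match(rec_genes, genes$name)]),
    samples = vapply(rec_genes, function(g) {
      paste(names(per_sample)[vapply(per_sample, function(v) g %in% v, NA)],
            collapse = ",")
    }, ""),
    stringsAsFactors = FALSE
  )
  recurrent <- recurrent[order(-recurrent$N, recurrent$gene), , drop = FALSE]
  rownames(recurrent) <- NULL
  list(per_sample = per_sample, recurrent = recurrent)
}
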