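# small file fixtures built in code

write_lines_tmp <- function(lines, ext = ".tsv") {
  p <- tempfile(fileext = ext)
  writeLines(lines, p)
  p
}

# hand-built ppgc_matrix for differential tests
make_ppgc <- function(raw, groups, gene_lengths = NULL) {
  samples <- data.frame(
    sample_id = colnames(raw), group = groups, stringsAsFactors = FALSE
  )
  if (is.null(gene_lengths)) {
    gene_lengths <- stats::setNames(rep(1000, nrow(raw)), rownames(raw))
  }
  l_max <- max(gene_lengths)
  scaled <- raw * (l_max / gene_lengths[rownames(raw)])
  structure(
    list(raw = raw, scaled = scaled, equalized = log2(scaled + 1),
         samples = samples, gene_lengths = gene_lengths, l_max = l_max),
    class = "ppgc_matrix"
  )
}

# ppgc_matrix whose *equalized* layer is given directly (raw kept binary
# consistent with zero/nonzero pattern)
make_ppgc_equalized <- function(eq, groups) {
  raw <- (eq > 0) * 1
  structure(
    list(raw = raw, scaled = raw, equalized = eq,
         samples = data.frame(sample_id = colnames(eq), group = groups,
                              stringsAsFactors = FALSE),
         gene_lengths = stats::setNames(rep(1000, nrow(eq)), rownames(eq)),
         l_max = 1000),
    class = "ppgc_matrix"
  )
}

small_cohort <- function(seed, ...) {
  cfg <- synth_config(seed = seed, ...)
  outdir <- file.path(tempfile("cohort"), "data")
  generate_cohort(cfg, outdir)
}

# module-level pipeline on a generated cohort (no result files written)
pipeline_core <- function(res, params = pipeline_params()) {
  manifest <- read_manifest(res$paths$manifest)
  genes <- read_gene_bed(res$paths$gene_bed)
  filtered <- lapply(read_catalogs(manifest), filter_chain, params = params)
  assignments <- lapply(filtered, annotate_circles, genes = genes)
  ppgc <- compute_ppgc(assignments, manifest)
  list(manifest = manifest, genes = genes, filtered = filtered,
       ppgc = ppgc, dppgc = select_dppgc(ppgc, params))
}
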