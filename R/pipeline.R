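#' Build a run configuration
#'
#' @param manifest path to the sample manifest TSV (sample_id, path, group).
#' @param gene_bed path to the BED4 gene annotation.
#' @param gmt optional character vector of GMT gene-set collection paths.
#' @param params a [pipeline_params()].
#' @param outdir output directory for all result tables.
#' @param case,control group labels; default control = alphabetically
#'   first label in the manifest.
#' @param bandwidth length-density kernel bandwidth (bp).
#' @param density_range length-density / CDF grid range (bp).
#' @param attribution multi-gene split-read attribution, see
#'   [compute_ppgc()].
#' @param verbose per-stage logging via [message()].
#' @return a `run_config` list.
#' @export
run_config <- function(manifest, gene_bed, gmt = character(),
                       params = pipeline_params(), outdir = "eccdiff_out",
                       case = NULL, control = NULL,
                       bandwidth = 10, density_range = c(0, 1000),
                       attribution = "full", verbose = TRUE) {
  structure(
    list(manifest = manifest, gene_bed = gene_bed, gmt = gmt,
         params = params, outdir = outdir, case = case, control = control,
         bandwidth = bandwidth, density_range = density_range,
         attribution = attribution, verbose = verbose),
    class = "run_config"
  )
}

#' Read a run configuration from YAML or JSON
#'
#' Recognised keys mirror the [run_config()] arguments; `params` is a
#' mapping with `l_max`, `d_min`, `jt_min`, `mito_names`, `theta_dppgc`,
#' `alpha_dppgc`, `alpha_wilcoxon`. Relative paths are resolved against
#' the config file's directory.
#'
#' @param path path to a `.yaml`/`.yml` or `.json` config file.
#' @return a `run_config`.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  base <- dirname(path)
  resolve <- function(p) {
    ifelse(file.exists(p) | grepl("^(/|[A-Za-z]:)", p), p, file.path(base, p))
  }
  params <- do.call(pipeline_params, as.list(raw$params))
  run_config(
    manifest = resolve(raw$manifest),
    gene_bed = resolve(raw$gene_bed),
    gmt = if (length(raw$gmt) > 0L) resolve(unlist(raw$gmt)) else character(),
    params = params,
    outdir = if (is.null(raw$outdir)) "eccdiff_out" else raw$outdir,
    case = raw$case, control = raw$control,
    bandwidth = if (is.null(raw$bandwidth)) 10 else raw$bandwidth,
    density_range = if (is.null(raw$density_range)) c(0, 1000)
                    else as.numeric(raw$density_range),
    attribution = if (is.null(raw$attribution)) "full" else raw$attribution,
    verbose = !isFALSE(raw$verbose)
  )
}

#' Run the full differential eccDNA pipeline
#'
#' Reads the manifest and catalogs, applies the filter chain per sample,
#' annotates circles with genes, builds the PpGC matrix, selects DPpGCs,
#' runs the whole-gene-carriage and fragment/whole analysis, computes the
#' length statistics, optionally runs enrichment of the up-in-case DPpGC
#' genes against supplied GMT collections (background: all genes of the
#' PpGC matrix), and writes every result table plus a run-manifest JSON
#' (parameters, L_Max, input checksums, package version) to the output
#' directory. The pipeline is fully deterministic: identical config and
#' inputs produce byte-identical outputs.
#'
#' @param config a [run_config()] or a path to a YAML/JSON config file.
#' @return invisibly, the named list of results (also written to disk):
#'   `catalogs`, `ppgc`, `dppgc`, `whole_genes`, `fragment_whole`,
#'   `counts`, `count_comparison`, `length_summary`, `enrichment`,
#'   `run_manifest`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_run_config(config)
  stopifnot(inherits(config, "run_config"))
  for (p in c(config$manifest, config$gene_bed, config$gmt)) {
    if (!file.exists(p)) stop("input file not found: ", p)
  }
  params <- config$params
  manifest <- read_manifest(config$manifest)
  genes <- read_gene_bed(config$gene_bed)
  catalogs <- read_catalogs(manifest)
  filtered <- lapply(catalogs, filter_chain, params = params,
                     verbose = config$verbose)
  assignments <- lapply(filtered, annotate_circles, genes = genes)
  ppgc <- compute_ppgc(assignments, manifest, attribution = config$attribution)
  labs <- resolve_groups(manifest$group, config$case, config$control)
  dppgc <- select_dppgc(ppgc, params, case = labs[["case"]],
                        control = labs[["control"]])
  whole <- whole_gene_carriage(filtered, genes)
  fw <- fragment_vs_whole_summary(dppgc, whole, ppgc$samples)
  counts <- vapply(filtered, count_unique, 0L)
  cmp <- compare_group_counts(counts, manifest, case = labs[["case"]],
                              control = labs[["control"]])
  ls_dens <- length_density(filtered, manifest, bandwidth = config$bandwidth,
                            range = config$density_range)
  grid <- ls_dens$grid
  cdf_mat <- vapply(filtered, function(ct) {
    if (nrow(ct) == 0L) rep(NA_real_, length(grid))
    else cumulative_curve(ct, config$density_range)$cdf
  }, numeric(length(grid)))
  length_summary <- list(
    density = data.frame(length_bp = grid, ls_dens$density,
                         sd = ls_dens$band, check.names = FALSE),
    peaks = ls_dens$peaks,
    cdf = data.frame(length_bp = grid, cdf_mat, check.names = FALSE),
    rhomboid = rhomboid_summary(filtered, manifest)
  )
  enr <- NULL
  if (length(config$gmt) > 0L) {
    up_case <- dppgc$gene[dppgc$direction == "up_in_case"]
    if (length(up_case) > 0L) {
      sets <- do.call(c, lapply(config$gmt, read_gmt))
      enr <- enrich(up_case, rownames(ppgc$raw), sets)
    } else if (config$verbose) {
      message("[enrich] no up-in-case DPpGC genes; enrichment skipped")
    }
  }
  run_manifest <- list(
    package = "eccdiff",
    version = as.character(utils::packageVersion("eccdiff")),
    params = unclass(params),
    case = labs[["case"]], control = labs[["control"]],
    l_max_gene = ppgc$l_max,
    n_samples = nrow(manifest),
    n_genes_quantified = nrow(ppgc$raw),
    n_dppgc = nrow(dppgc),
    inputs = as.list(tools::md5sum(c(config$manifest, config$gene_bed,
                                     manifest$path, config$gmt)))
  )
  results <- list(
    catalogs = filtered, ppgc = ppgc, dppgc = dppgc, whole_genes = whole,
    fragment_whole = fw,
    counts = data.frame(sample_id = names(counts),
                        group = manifest$group[match(names(counts),
                                                     manifest$sample_id)],
                        unique_circles = as.integer(counts),
                        stringsAsFactors = FALSE),
    count_comparison = cmp, length_summary = length_summary,
    enrichment = enr, run_manifest = run_manifest
  )
  write_results(results, config$outdir)
  if (!is.null(fw) && nrow(fw) > 0L) {
    write_tsv(fw, file.path(config$outdir, "fragment_vs_whole.tsv"))
  }
  invisible(results)
}
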