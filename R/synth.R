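#' Synthetic cohort configuration
#'
#' Describes a two-group cell-free eccDNA cohort with the statistical
#' structure the pipeline assumes: log-normal per-sample circle counts
#' differing ~30x between groups, circle lengths from a nucleosome-periodic
#' Gaussian mixture (peaks near 200 and 350 bp) plus a long-tail component
#' that is heavier in the case group, genic placement of a configurable
#' fraction of circles, a planted set of case-specific genes receiving
#' well-supported fragment circles in every case sample and none in
#' controls, and noise knobs (sub-threshold single-split-read circles,
#' mitochondrial circles, over-length circles) that exercise every filter.
#'
#' Default per-sample count means are the published group means scaled
#' down 10x (55 vs 1700) to keep test runtimes small; pass the printed
#' means (552, 17212) for a paper-scale cohort.
#'
#' @param seed mandatory PRNG seed (integer).
#' @param n_control,n_case samples per group.
#' @param genome named numeric vector of chromosome lengths (bp); must
#'   include one mitochondrial alias.
#' @param n_genes genes placed on the non-mitochondrial chromosomes.
#' @param gene_length_range gene length range (bp).
#' @param count_mean named vector `control`, `case`: mean circles/sample.
#' @param count_sdlog named vector: log-normal sdlog per group.
#' @param length_peaks Gaussian mixture peak locations (bp).
#' @param length_peak_sd common peak standard deviation (bp).
#' @param mix_weights_control,mix_weights_case mixture weights (peaks...,
#'   long tail); each must sum to 1.
#' @param tail_offset,tail_mean long-tail component: offset + Exp(mean).
#' @param genic_fraction probability a circle is placed inside a gene.
#' @param n_planted number of planted case-specific genes.
#' @param planted_circles circles per planted gene per case sample.
#' @param planted_split_reads baseline split reads of planted circles.
#' @param frac_single_read fraction of base circles downgraded to 1 split
#'   read (removed by the support filter unless merged).
#' @param frac_mito expected mitochondrial noise circles, as a fraction of
#'   the base count.
#' @param frac_over_lmax expected over-length (>10 kb) noise circles,
#'   likewise.
#' @param group_labels named vector `control`, `case` of group labels.
#' @return a `synth_config` list.
#' @export
synth_config <- function(seed,
                         n_control = 6L, n_case = 4L,
                         genome = c(chr1 = 1e7, chr2 = 1e7, chr3 = 1e7,
                                    chrM = 16569),
                         n_genes = 205L,
                         gene_length_range = c(1000, 20000),
                         count_mean = c(control = 55, case = 1700),
                         count_sdlog = c(control = 0.45, case = 0.5),
                         length_peaks = c(200, 350),
                         length_peak_sd = 15,
                         mix_weights_control = c(0.55, 0.35, 0.10),
                         mix_weights_case = c(0.45, 0.30, 0.25),
                         tail_offset = 400, tail_mean = 800,
                         genic_fraction = 0.6,
                         n_planted = 5L,
                         planted_circles = 3L,
                         planted_split_reads = 100,
                         frac_single_read = 0.10,
                         frac_mito = 0.02,
                         frac_over_lmax = 0.02,
                         group_labels = c(control = "HC", case = "SLE")) {
  if (missing(seed)) stop("synth_config: seed is mandatory")
  stopifnot(
    n_control >= 1L, n_case >= 1L, n_genes >= 1L, n_planted <= n_genes,
    length(mix_weights_control) == length(length_peaks) + 1L,
    length(mix_weights_case) == length(length_peaks) + 1L,
    abs(sum(mix_weights_control) - 1) < 1e-9,
    abs(sum(mix_weights_case) - 1) < 1e-9,
    all(mix_weights_control >= 0), all(mix_weights_case >= 0),
    genic_fraction >= 0, genic_fraction <= 1,
    frac_single_read >= 0, frac_single_read <= 1,
    frac_mito >= 0, frac_mito <= 1, frac_over_lmax >= 0, frac_over_lmax <= 1,
    gene_length_range[1L] > 0, gene_length_range[1L] <= gene_length_range[2L]
  )
  mito <- names(genome)[names(genome) %in% c("chrM", "chrMT", "MT", "M")]
  if (length(mito) != 1L) stop("genome must contain exactly one mitochondrial chromosome")
  structure(as.list(environment()), class = "synth_config")
}

# run code with a private, seeded RNG stream, restoring global state after
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Generate a synthetic gene annotation
#'
#' Places `n_genes` non-overlapping genes on the non-mitochondrial
#' chromosomes (round-robin), with lengths uniform in `gene_length_range`
#' and random inter-gene gaps. Deterministic under the config seed.
#'
#' @param config a [synth_config()].
#' @return a [gene_annotation()].
#' @export
generate_annotation <- function(config) {
  with_seed(config$seed, {
    chroms <- setdiff(names(config$genome), config$mito)
    lens <- sample(seq(config$gene_length_range[1L], config$gene_length_range[2L]),
                   config$n_genes, replace = TRUE)
    chrom_of <- rep(chroms, length.out = config$n_genes)
    rows <- lapply(chroms, function(chr) {
      i <- which(chrom_of == chr)
      if (length(i) == 0L) return(NULL)
      li <- lens[i]
      cap <- config$genome[[chr]]
      free <- cap - sum(li)
      if (free < 100 * (length(i) + 1L)) {
        stop("genome too small for requested genes on ", chr)
      }
      u <- stats::runif(length(i) + 1L)
      gaps <- floor(free * u / sum(u))
      starts <- cumsum(gaps[seq_along(i)]) + c(0, cumsum(li[-length(li)]))
      data.frame(chrom = chr, start = starts, end = starts + li,
                 name = sprintf("GENE_%04d", i), stringsAsFactors = FALSE)
    })
    gene_annotation(do.call(rbind, rows))
  })
}

#' Generate a synthetic two-group cohort on disk
#'
#' Writes per-sample circle-call tables, the gene BED, a sample manifest
#' and a ground-truth JSON to `outdir`. Planted genes receive
#' `planted_circles` fragment circles (never containing the whole gene)
#' with ~`planted_split_reads` split reads in every case sample and no
#' circles at all in control samples; randomly placed circles avoid the
#' planted genes so planting is the only signal there. Byte-identical
#' outputs under the same config.
#'
#' @param config a [synth_config()].
#' @param outdir output directory (created if needed).
#' @return list with `manifest` (data.frame sample_id, path, group),
#'   `annotation`, `truth` (planted genes, per-sample base counts, seed)
#'   and `paths` (named file paths).
#' @export
generate_cohort <- function(config, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  ann <- generate_annotation(config)
  auto <- setdiff(names(config$genome), config$mito)
  auto_len <- unlist(config$genome[auto])
  with_seed(config$seed + 1L, {
    planted <- sort(sample(ann$name, config$n_planted))
    open_genes <- ann[!(ann$name %in% planted), , drop = FALSE]
    planted_ann <- ann[ann$name %in% planted, , drop = FALSE]
    sample_ids <- c(
      sprintf("%s%d", config$group_labels[["control"]], seq_len(config$n_control)),
      sprintf("%s%d", config$group_labels[["case"]], seq_len(config$n_case))
    )
    groups <- c(rep(config$group_labels[["control"]], config$n_control),
                rep(config$group_labels[["case"]], config$n_case))
    base_counts <- integer(length(sample_ids))
    paths <- character(length(sample_ids))
    for (si in seq_along(sample_ids)) {
      is_case <- groups[si] == config$group_labels[["case"]]
      grp_key <- if (is_case) "case" else "control"
      mu <- config$count_mean[[grp_key]]
      sdl <- config$count_sdlog[[grp_key]]
      n_circ <- max(1L, round(stats::rlnorm(1, log(mu) - sdl^2 / 2, sdl)))
      base_counts[si] <- n_circ
      lens <- draw_lengths(n_circ, config, grp_key)
      place <- place_circles(n_circ, lens, config, open_genes, planted_ann,
                             auto, auto_len)
      sr <- 2 + stats::rgeom(n_circ, 0.5)   # JT_min + shifted geometric
      n_single <- floor(config$frac_single_read * n_circ)
      if (n_single > 0L) sr[sample.int(n_circ, n_single)] <- 1
      df <- data.frame(chrom = place$chrom, start = place$start,
                       end = place$end, split_reads = sr,
                       stringsAsFactors = FALSE)
      # mitochondrial noise
      n_mito <- stats::rbinom(1, n_circ, config$frac_mito)
      if (n_mito > 0L) {
        ml <- pmin(round(draw_lengths(n_mito, config, grp_key)),
                   config$genome[[config$mito]] - 1)
        ms <- floor(stats::runif(n_mito, 0, config$genome[[config$mito]] - ml))
        df <- rbind(df, data.frame(chrom = config$mito, start = ms,
                                   end = ms + ml,
                                   split_reads = 2 + stats::rgeom(n_mito, 0.5)))
      }
      # over-length noise (> 10 kb)
      n_big <- stats::rbinom(1, n_circ, config$frac_over_lmax)
      if (n_big > 0L) {
        bl <- round(stats::runif(n_big, 10001, 50000))
        bc <- sample(auto, n_big, replace = TRUE, prob = auto_len)
        bs <- floor(stats::runif(n_big, 0, auto_len[bc] - bl))
        df <- rbind(df, data.frame(chrom = bc, start = bs, end = bs + bl,
                                   split_reads = 2 + stats::rgeom(n_big, 0.5)))
      }
      # planted case-specific fragment circles
      if (is_case && nrow(planted_ann) > 0L) {
        for (gi in seq_len(nrow(planted_ann))) {
          g <- planted_ann[gi, ]
          k <- config$planted_circles
          pl <- pmin(pmax(round(stats::rnorm(k, 350, 15)), 100), g$length - 1)
          ps <- g$start + floor(stats::runif(k, 0, g$length - pl))
          df <- rbind(df, data.frame(
            chrom = g$chrom, start = ps, end = ps + pl,
            split_reads = config$planted_split_reads + stats::rpois(k, 20)
          ))
        }
      }
      p <- file.path(outdir, paste0(sample_ids[si], ".circles.tsv"))
      write_catalog(circle_catalog(df, sample_ids[si], groups[si]), p)
      paths[si] <- p
    }
    manifest <- data.frame(sample_id = sample_ids,
                           path = paths, group = groups,
                           stringsAsFactors = FALSE)
    bed_path <- file.path(outdir, "genes.bed")
    writeLines(sprintf("%s\t%d\t%d\t%s", ann$chrom, as.integer(ann$start),
                       as.integer(ann$end), ann$name), bed_path)
    man_path <- file.path(outdir, "manifest.tsv")
    utils::write.table(manifest, man_path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = TRUE)
    truth <- list(
      planted_genes = planted,
      base_counts = stats::setNames(as.list(base_counts), sample_ids),
      seed = config$seed,
      count_mean = as.list(config$count_mean),
      group_labels = as.list(config$group_labels)
    )
    truth_path <- file.path(outdir, "truth.json")
    jsonlite::write_json(truth, truth_path, auto_unbox = TRUE, pretty = TRUE)
    list(manifest = manifest, annotation = ann, truth = truth,
         paths = list(manifest = man_path, gene_bed = bed_path,
                      truth = truth_path))
  })
}

# circle lengths from the group's mixture: Gaussian peaks + shifted-Exp tail
draw_lengths <- function(n, config, grp_key) {
  w <- if (grp_key == "case") config$mix_weights_case else config$mix_weights_control
  comp <- sample.int(length(w), n, replace = TRUE, prob = w)
  n_peak <- length(config$length_peaks)
  len <- numeric(n)
  for (i in seq_len(n_peak)) {
    idx <- comp == i
    len[idx] <- stats::rnorm(sum(idx), config$length_peaks[i], config$length_peak_sd)
  }
  tail_idx <- comp == n_peak + 1L
  len[tail_idx] <- config$tail_offset + stats::rexp(sum(tail_idx), 1 / config$tail_mean)
  pmax(50, round(len))
}

# place circles: genic ones inside a random non-planted gene, the rest
# uniform on the autosomes but never overlapping a planted gene
place_circles <- function(n, lens, config, open_genes, planted_ann,
                          auto, auto_len) {
  genic <- stats::runif(n) < config$genic_fraction
  chrom <- character(n); start <- numeric(n)
  if (any(genic)) {
    gi <- sample.int(nrow(open_genes), sum(genic), replace = TRUE)
    chrom[genic] <- open_genes$chrom[gi]
    start[genic] <- open_genes$start[gi] +
      floor(stats::runif(sum(genic), 0, open_genes$length[gi]))
  }
  inter <- which(!genic)
  if (length(inter) > 0L) {
    ic <- sample(auto, length(inter), replace = TRUE, prob = auto_len)
    ip <- floor(stats::runif(length(inter), 0, pmax(1, auto_len[ic] - lens[inter])))
    for (tries in 1:100) {
      bad <- overlaps_planted(ic, ip, ip + lens[inter], planted_ann)
      if (!any(bad)) break
      ic[bad] <- sample(auto, sum(bad), replace = TRUE, prob = auto_len)
      ip[bad] <- floor(stats::runif(sum(bad), 0,
                                    pmax(1, auto_len[ic[bad]] - lens[inter][bad])))
    }
    chrom[inter] <- ic
    start[inter] <- ip
  }
  end <- start + lens
  # keep circles inside their chromosome
  cap <- unlist(config$genome)[chrom]
  shift <- pmax(0, end - cap)
  start <- pmax(0, start - shift)
  list(chrom = chrom, start = start, end = start + lens)
}

overlaps_planted <- function(chrom, start, end, planted_ann) {
  if (nrow(planted_ann) == 0L) return(rep(FALSE, length(chrom)))
  bad <- rep(FALSE, length(chrom))
  for (i in seq_len(nrow(planted_ann))) {
    g <- planted_ann[i, ]
    bad <- bad | (chrom == g$chrom & start < g$end & end > g$start)
  }
  bad
}
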