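#' Remove mitochondrial and over-length circles
#'
#' First stage of the catalog-cleaning chain: drops calls on mitochondrial
#' chromosome aliases and calls longer than `l_max`. Both rules are read
#' strictly: a call of length exactly `l_max` is kept.
#'
#' @param catalog a [circle_catalog()].
#' @param params a [pipeline_params()].
#' @return a filtered `circle_catalog`.
#' @export
filter_mito_and_length <- function(catalog, params = pipeline_params()) {
  keep <- !(catalog$chrom %in% params$mito_names) & catalog$length <= params$l_max
  catalog_like(catalog, catalog[keep, , drop = FALSE])
}

#' Merge clusters of near-identical circles
#'
#' Two circles are linked when both their breakpoints are within `d_min`:
#' d(a, b) = max(|a.start - b.start|, |a.end - b.end|) < d_min, on the same
#' chromosome. Clusters are the connected components of this relation
#' (single linkage, so chains merge transitively). Each cluster collapses
#' to one call at the coordinates of the best-supported member (largest
#' split_reads; ties broken by smallest start, then smallest end), with
#' split reads summed over the cluster — total split reads are conserved.
#'
#' @param catalog a [circle_catalog()].
#' @param d_min merge distance in bp; linkage requires strict `< d_min`.
#' @return merged `circle_catalog`, sorted.
#' @export
merge_circles <- function(catalog, d_min = 10) {
  n <- nrow(catalog)
  if (n < 2L || d_min <= 0) return(catalog_like(catalog, catalog))
  comp <- integer(n)      # global cluster id
  next_id <- 0L
  for (chr in unique(catalog$chrom)) {
    idx <- which(catalog$chrom == chr)
    m <- length(idx)
    s <- catalog$start[idx]
    e <- catalog$end[idx]
    parent <- seq_len(m)
    find <- function(i) {
      while (parent[i] != i) {
        parent[i] <<- parent[parent[i]]
        i <- parent[i]
      }
      i
    }
    # calls are sorted by start, so linkage candidates lie in a d_min window
    for (i in seq_len(m - 1L)) {
      j <- i + 1L
      while (j <= m && s[j] - s[i] < d_min) {
        if (abs(e[j] - e[i]) < d_min) {
          ri <- find(i); rj <- find(j)
          if (ri != rj) parent[rj] <- ri
        }
        j <- j + 1L
      }
    }
    roots <- vapply(seq_len(m), find, 0L)
    comp[idx] <- next_id + match(roots, unique(roots))
    next_id <- next_id + length(unique(roots))
  }
  # representative: max split_reads, tie -> smallest start, then smallest end
  ord <- order(comp, -catalog$split_reads, catalog$start, catalog$end)
  reps <- ord[!duplicated(comp[ord])]   # one row per cluster, cluster ids ascending
  rep_df <- catalog[reps, c("chrom", "start", "end"), drop = FALSE]
  f <- factor(comp, levels = seq_len(next_id))
  rep_df$split_reads <- as.numeric(tapply(catalog$split_reads, f, sum))
  catalog_like(catalog, rep_df)
}

#' Remove circles below the split-read support threshold
#'
#' Applied after merging, so that several sub-threshold calls merging into
#' one well-supported circle survive.
#'
#' @param catalog a [circle_catalog()].
#' @param jt_min minimum split reads retained (`>= jt_min` kept).
#' @return filtered `circle_catalog`.
#' @export
filter_split_reads <- function(catalog, jt_min = 2) {
  catalog_like(catalog, catalog[catalog$split_reads >= jt_min, , drop = FALSE])
}

#' Run the full catalog-cleaning chain
#'
#' Stage order is fixed: mitochondrial/length filter, then proximity
#' merging, then the split-read filter.
#'
#' @param catalog a [circle_catalog()].
#' @param params a [pipeline_params()].
#' @param verbose emit per-stage call counts with [message()].
#' @return cleaned `circle_catalog` with attribute `filter_log`, a named
#'   integer vector of call counts after each stage.
#' @export
filter_chain <- function(catalog, params = pipeline_params(), verbose = FALSE) {
  n0 <- nrow(catalog)
  a <- filter_mito_and_length(catalog, params)
  b <- merge_circles(a, params$d_min)
  c_ <- filter_split_reads(b, params$jt_min)
  log <- c(input = n0, after_mito_length = nrow(a),
           after_merge = nrow(b), after_split_read = nrow(c_))
  if (verbose) {
    message(sprintf(
      "[filter] %s: %d -> %d (mito/length) -> %d (merge) -> %d (split reads)",
      sample_id(catalog), n0, nrow(a), nrow(b), nrow(c_)
    ))
  }
  attr(c_, "filter_log") <- log
  c_
}
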