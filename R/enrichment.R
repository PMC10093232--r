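#' Hypergeometric over-representation analysis
#'
#' Stand-in for web-based term enrichment: for each gene set, counts the
#' signal genes (k) and background genes (K) among the set's members and
#' computes the hypergeometric upper-tail probability
#' P[X >= k], X ~ Hypergeometric(N, K, n), with N the background size and
#' n the signal size. Matching is case-insensitive. Signal genes missing
#' from the background are dropped with a warning; terms with K = 0 are
#' skipped.
#'
#' @param signal character vector of signal gene symbols (e.g. the
#'   up-DPpGC genes).
#' @param background character vector of background gene symbols (the
#'   assayed genic universe, e.g. all genes of the PpGC matrix).
#' @param sets gene-set collection from [read_gmt()].
#' @param bh apply Benjamini-Hochberg adjustment (extra column `p_adj`).
#' @return data.frame ordered by ascending p then term_id: `term_id`,
#'   `term_name`, `k`, `K`, `n`, `N`, `p_value`, `member_genes`
#'   (comma-separated overlapping symbols).
#' @export
enrich <- function(signal, background, sets, bh = FALSE) {
  if (length(sets) == 0L) stop("empty gene-set collection")
  signal <- unique(toupper(signal))
  background <- unique(toupper(background))
  out_of_bg <- setdiff(signal, background)
  if (length(out_of_bg) > 0L) {
    warning(length(out_of_bg), " signal gene(s) absent from background dropped")
    signal <- setdiff(signal, out_of_bg)
  }
  if (length(signal) == 0L) stop("empty signal set after intersecting with background")
  n <- length(signal)
  N <- length(background)
  rows <- lapply(sets, function(s) {
    members_bg <- intersect(s$members, background)
    K <- length(members_bg)
    if (K == 0L) return(NULL)
    hit <- intersect(members_bg, signal)
    k <- length(hit)
    p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    data.frame(term_id = s$term_id, term_name = s$term_name,
               k = k, K = K, n = n, N = N, p_value = p,
               member_genes = paste(sort(hit), collapse = ","),
               stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, NA)]
  if (length(rows) == 0L) {
    return(data.frame(term_id = character(), term_name = character(),
                      k = integer(), K = integer(), n = integer(),
                      N = integer(), p_value = numeric(),
                      member_genes = character(), stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  if (bh) out$p_adj <- stats::p.adjust(out$p_value, method = "BH")
  out <- out[order(out$p_value, out$term_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Intersect a gene list with a named catalog of genes
#'
#' Plain case-insensitive gene-list intersection, e.g. against a disease
#' variant catalog.
#'
#' @param signal character vector of gene symbols.
#' @param catalog character vector of gene symbols to intersect with.
#' @return list with `overlap` (sorted symbols), `n_overlap`, `n_signal`,
#'   `n_catalog`.
#' @export
overlap_catalog <- function(signal, catalog) {
  stopifnot(length(signal) > 0L, length(catalog) > 0L)
  s <- unique(toupper(signal))
  c_ <- unique(toupper(catalog))
  ov <- sort(intersect(s, c_))
  list(overlap = ov, n_overlap = length(ov),
       n_signal = length(s), n_catalog = length(c_))
}
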