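# Independent brute-force oracles used to cross-check the fast paths.

# O(n^2) single-linkage merge: link circles on the same chromosome with
# max(|dstart|, |dend|) < d_min, take connected components, collapse each
# to (coords of max-split_reads member, summed split reads).
brute_merge <- function(df, d_min) {
  n <- nrow(df)
  if (n == 0L) return(df[0, ])
  comp <- seq_len(n)
  repeat {
    changed <- FALSE
    for (i in seq_len(n)) {
      for (j in seq_len(n)) {
        if (df$chrom[i] == df$chrom[j] &&
            max(abs(df$start[i] - df$start[j]), abs(df$end[i] - df$end[j])) < d_min &&
            comp[i] != comp[j]) {
          comp[comp == comp[j]] <- comp[i]
          changed <- TRUE
        }
      }
    }
    if (!changed) break
  }
  rows <- lapply(unique(comp), function(cc) {
    sub <- df[comp == cc, , drop = FALSE]
    sub <- sub[order(-sub$split_reads, sub$start, sub$end), , drop = FALSE]
    data.frame(chrom = sub$chrom[1], start = sub$start[1], end = sub$end[1],
               split_reads = sum(sub$split_reads), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$chrom, out$start, out$end), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# all-pairs half-open interval overlap
brute_overlap <- function(circles, genes) {
  hits <- list()
  for (i in seq_len(nrow(circles))) {
    for (j in seq_len(nrow(genes))) {
      if (circles$chrom[i] == genes$chrom[j] &&
          circles$start[i] < genes$end[j] && genes$start[j] < circles$end[i]) {
        hits[[length(hits) + 1L]] <- c(i, j)
      }
    }
  }
  if (length(hits) == 0L) {
    return(data.frame(circle = integer(), gene_row = integer()))
  }
  m <- do.call(rbind, hits)
  out <- data.frame(circle = m[, 1], gene_row = m[, 2])
  out[order(out$circle, out$gene_row), ]
}

# textbook pooled-variance two-sample t
ttest_textbook <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  s2 <- (sum((x - mean(x))^2) + sum((y - mean(y))^2)) / (n1 + n2 - 2)
  t <- (mean(x) - mean(y)) / sqrt(s2 * (1 / n1 + 1 / n2))
  list(t = t, p = 2 * pt(-abs(t), n1 + n2 - 2))
}

# hypergeometric upper tail by direct summation of the pmf
hyper_tail <- function(N, K, n, k) {
  i <- k:min(K, n)
  sum(choose(K, i) * choose(N - K, n - i)) / choose(N, n)
}

random_catalog <- function(n, chroms = c("chr1", "chr2"), maxpos = 500,
                           sample = "s", group = "G") {
  start <- sample.int(maxpos, n, replace = TRUE)
  len <- sample.int(60, n, replace = TRUE)
  circle_catalog(
    data.frame(chrom = sample(chroms, n, replace = TRUE),
               start = start, end = start + len,
               split_reads = sample.int(5, n, replace = TRUE)),
    sample_id = sample, group = group
  )
}

# the constructed 10-circle toy exercising every stage of the filter chain:
# 2 mitochondrial, 1 over-length (12 kb), 2 one-read circles that merge
# into a surviving 2-read circle, 2 one-read singletons that are removed,
# 3 ordinary circles that pass untouched
toy_filter_catalog <- function() {
  circle_catalog(data.frame(
    chrom = c("chrM", "chrM", "chr1", "chr1", "chr1",
              "chr2", "chr3", "chr1", "chr2", "chr3"),
    start = c(0, 10, 0, 100, 105, 1000, 50, 2000, 5000, 7000),
    end = c(300, 200, 12000, 500, 495, 1300, 400, 2500, 5600, 7800),
    split_reads = c(9, 5, 4, 1, 1, 1, 1, 3, 2, 7)
  ), sample_id = "toy", group = "T")
}
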