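#' Number of unique circles in a catalog
#'
#' Counts distinct (chrom, start, end) intervals; on a catalog that has
#' been through [read_circle_table()] or [filter_chain()] this is simply
#' the number of calls.
#'
#' @param catalog a [circle_catalog()].
#' @return integer count.
#' @export
count_unique <- function(catalog) {
  nrow(unique(as.data.frame(catalog)[c("chrom", "start", "end")]))
}

#' Exact Wilcoxon rank-sum test
#'
#' For combined sample sizes up to `exact_max` the null distribution of the
#' rank sum is obtained by full enumeration of all choose(n1+n2, n1)
#' assignments of the (mid)ranks, which handles ties exactly (conditional
#' on the observed tie pattern). Above that a normal approximation with
#' tie correction and continuity correction is used.
#'
#' @param x,y numeric vectors (the two groups).
#' @param exact_max largest n1+n2 for which full enumeration is used.
#' @return list with `w` (rank sum of `x`), `p_less`, `p_greater`,
#'   `p_two_sided` and `method` (`"exact"` or `"normal"`).
#' @export
wilcoxon_rank_sum <- function(x, y, exact_max = 12L) {
  n1 <- length(x); n2 <- length(y); n <- n1 + n2
  stopifnot(n1 >= 1L, n2 >= 1L)
  r <- rank(c(x, y))
  w <- sum(r[seq_len(n1)])
  eps <- 1e-8
  if (n <= exact_max) {
    cmb <- utils::combn(n, n1)
    w_all <- colSums(matrix(r[cmb], nrow = n1))
    p_less <- mean(w_all <= w + eps)
    p_greater <- mean(w_all >= w - eps)
    method <- "exact"
  } else {
    mu <- n1 * (n + 1) / 2
    ties <- table(r)
    sigma2 <- n1 * n2 / 12 * ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
    sigma <- sqrt(sigma2)
    p_less <- stats::pnorm(w + 0.5, mu, sigma)
    p_greater <- stats::pnorm(w - 0.5, mu, sigma, lower.tail = FALSE)
    method <- "normal"
  }
  list(w = w, p_less = p_less, p_greater = p_greater,
       p_two_sided = min(1, 2 * min(p_less, p_greater)), method = method)
}

#' Compare per-sample circle counts between groups
#'
#' Per-group mean and standard error of the per-sample unique-circle
#' counts, an exact Wilcoxon rank-sum comparison, and the fold ratio
#' mean(control)/mean(case). The headline p-value (`p_one_sided`) is the
#' one-sided exact p in the direction of the observed mean difference; the
#' two-sided p is reported alongside.
#'
#' @param counts named numeric vector of per-sample circle counts (names
#'   are sample ids).
#' @param manifest data.frame `sample_id`, `group` covering the counts.
#' @param case,control group labels (default: alphabetically second label
#'   is the case).
#' @return a `group_count_comparison` data.frame (one row) with columns
#'   `group_control`, `group_case`, `n_control`, `n_case`, `mu_control`,
#'   `sem_control`, `mu_case`, `sem_case`, `fold_ratio`, `p_one_sided`,
#'   `p_two_sided`, `method`.
#' @export
compare_group_counts <- function(counts, manifest, case = NULL, control = NULL) {
  labs <- resolve_groups(manifest$group, case, control)
  g <- manifest$group[match(names(counts), manifest$sample_id)]
  if (anyNA(g)) stop("counts contain samples absent from the manifest")
  x_ctrl <- counts[g == labs["control"]]
  x_case <- counts[g == labs["case"]]
  if (length(x_ctrl) < 2L || length(x_case) < 2L) {
    stop("group with <2 samples")
  }
  wt <- wilcoxon_rank_sum(x_ctrl, x_case)
  p_one <- if (mean(x_ctrl) <= mean(x_case)) wt$p_less else wt$p_greater
  sem <- function(v) stats::sd(v) / sqrt(length(v))
  out <- data.frame(
    group_control = unname(labs["control"]), group_case = unname(labs["case"]),
    n_control = length(x_ctrl), n_case = length(x_case),
    mu_control = mean(x_ctrl), sem_control = sem(x_ctrl),
    mu_case = mean(x_case), sem_case = sem(x_case),
    fold_ratio = mean(x_ctrl) / mean(x_case),
    p_one_sided = p_one, p_two_sided = wt$p_two_sided,
    method = wt$method, stringsAsFactors = FALSE
  )
  class(out) <- c("group_count_comparison", "data.frame")
  out
}

# Gaussian kernel density of circle lengths on a 1-bp grid, renormalized to
# integrate to 1 over the grid (rectangle rule, 1-bp spacing).
kernel_density_grid <- function(lengths, grid, bandwidth) {
  d <- stats::density(lengths, bw = bandwidth, kernel = "gaussian",
                      from = grid[1L], to = grid[length(grid)], n = length(grid))
  y <- d$y
  total <- sum(y)
  if (total <= 0) return(rep(0, length(grid)))
  y / total
}

local_maxima <- function(y) {
  n <- length(y)
  if (n < 3L) return(integer())
  which(y[2:(n - 1)] > y[1:(n - 2)] & y[2:(n - 1)] > y[3:n]) + 1L
}

#' Smoothed length distributions with local maxima
#'
#' Per-group Gaussian-kernel density of circle lengths on a 1-bp grid,
#' renormalized to integrate to 1 over the stated range; local maxima are
#' grid points strictly greater than both neighbours. A per-group
#' across-sample standard-deviation band is computed from the per-sample
#' densities.
#'
#' @param catalogs named list of [circle_catalog()]s.
#' @param manifest data.frame `sample_id`, `group`.
#' @param bandwidth Gaussian kernel standard deviation (bp).
#' @param range numeric length-2 vector, grid limits in bp.
#' @param peak_min_frac numerical guard for peak calling: maxima whose
#'   density is below this fraction of the group maximum are floating-point
#'   ripples in the far tail of the kernel estimate, not real modes, and
#'   are discarded.
#' @return list with `grid`, `density` (matrix grid x groups), `band` (sd
#'   across samples, same shape), `peaks` (data.frame group, length_bp,
#'   density) and `empty_groups` (labels with no circle in range).
#' @export
length_density <- function(catalogs, manifest, bandwidth = 10,
                           range = c(0, 1000), peak_min_frac = 1e-6) {
  stopifnot(bandwidth > 0, length(range) == 2L, range[1L] < range[2L])
  grid <- seq(range[1L], range[2L], by = 1)
  g_of <- function(cat_i) manifest$group[match(sample_id(cat_i), manifest$sample_id)]
  groups <- sort(unique(manifest$group))
  dens <- matrix(0, nrow = length(grid), ncol = length(groups),
                 dimnames = list(NULL, groups))
  band <- dens
  empty_groups <- character()
  peaks <- NULL
  for (grp in groups) {
    cats <- catalogs[vapply(catalogs, g_of, "") == grp]
    lens <- unlist(lapply(cats, function(ct) ct$length), use.names = FALSE)
    lens_in <- lens[lens >= range[1L] & lens <= range[2L]]
    if (length(lens_in) == 0L) {
      empty_groups <- c(empty_groups, grp)
      next
    }
    dens[, grp] <- kernel_density_grid(lens_in, grid, bandwidth)
    per_sample <- vapply(cats, function(ct) {
      li <- ct$length[ct$length >= range[1L] & ct$length <= range[2L]]
      if (length(li) == 0L) rep(0, length(grid))
      else kernel_density_grid(li, grid, bandwidth)
    }, numeric(length(grid)))
    band[, grp] <- apply(per_sample, 1, stats::sd)
    pk <- local_maxima(dens[, grp])
    pk <- pk[dens[pk, grp] >= peak_min_frac * max(dens[, grp])]
    if (length(pk) > 0L) {
      peaks <- rbind(peaks, data.frame(group = grp, length_bp = grid[pk],
                                       density = dens[pk, grp],
                                       stringsAsFactors = FALSE))
    }
  }
  if (is.null(peaks)) {
    peaks <- data.frame(group = character(), length_bp = numeric(),
                        density = numeric(), stringsAsFactors = FALSE)
  }
  rownames(peaks) <- NULL
  list(grid = grid, density = dens, band = band, peaks = peaks,
       empty_groups = empty_groups)
}

#' Empirical cumulative length curve
#'
#' Empirical CDF of a catalog's circle lengths evaluated on a 1-bp grid
#' over `range`. When every length lies beyond the range the curve is
#' identically zero inside it and `in_range` is FALSE.
#'
#' @param catalog a [circle_catalog()].
#' @param range numeric length-2 vector (bp).
#' @return list with `grid`, `cdf` and `in_range`.
#' @export
cumulative_curve <- function(catalog, range = c(0, 1000)) {
  stopifnot(nrow(catalog) > 0L)
  grid <- seq(range[1L], range[2L], by = 1)
  f <- stats::ecdf(catalog$length)
  cdf <- f(grid)
  list(grid = grid, cdf = cdf,
       in_range = any(catalog$length >= range[1L] & catalog$length <= range[2L]))
}

#' Rhomboid (mu, sigma) summaries per group
#'
#' For each group: mean and sample (n-1) standard deviation of the pooled
#' circle lengths, and of the per-sample circle counts. The rhomboid
#' vertices are (mu - sigma, mu, mu + sigma) on each axis. A single-sample
#' group has an undefined count sd, reported as 0 with a warning.
#'
#' @param catalogs named list of [circle_catalog()]s.
#' @param manifest data.frame `sample_id`, `group`.
#' @return data.frame, one row per group: `group`, `n_samples`,
#'   `length_mu`, `length_sigma`, `count_mu`, `count_sigma` and the six
#'   vertex columns `length_lo/mid/hi`, `count_lo/mid/hi`.
#' @export
rhomboid_summary <- function(catalogs, manifest) {
  g_of <- function(cat_i) manifest$group[match(sample_id(cat_i), manifest$sample_id)]
  groups <- sort(unique(manifest$group))
  rows <- lapply(groups, function(grp) {
    cats <- catalogs[vapply(catalogs, g_of, "") == grp]
    lens <- unlist(lapply(cats, function(ct) ct$length), use.names = FALSE)
    counts <- vapply(cats, count_unique, 0L)
    lmu <- mean(lens)
    lsd <- if (length(lens) > 1L) stats::sd(lens) else 0
    cmu <- mean(counts)
    if (length(counts) > 1L) {
      csd <- stats::sd(counts)
    } else {
      warning("group ", grp, " has a single sample; count sigma reported as 0")
      csd <- 0
    }
    data.frame(group = grp, n_samples = length(cats),
               length_mu = lmu, length_sigma = lsd,
               count_mu = cmu, count_sigma = csd,
               length_lo = lmu - lsd, length_mid = lmu, length_hi = lmu + lsd,
               count_lo = cmu - csd, count_mid = cmu, count_hi = cmu + csd,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
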