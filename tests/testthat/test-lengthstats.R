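test_that("count_unique counts distinct intervals after the filter chain", {
  cat1 <- circle_catalog(data.frame(
    chrom = "chr1", start = c(0, 100, 400), end = c(50, 300, 600),
    split_reads = c(2, 3, 4)), "s", "G")
  expect_equal(count_unique(cat1), 3L)
  expect_equal(count_unique(filter_split_reads(cat1, 99)), 0L)
  # hand-traced toy: full chain leaves 4 unique circles
  expect_equal(count_unique(filter_chain(toy_filter_catalog())), 4L)
})

test_that("exact Wilcoxon matches closed forms and wilcox.test", {
  # complete separation at 6 vs 4: one-sided p = 1/C(10,4)
  w <- wilcoxon_rank_sum(c(1, 2, 3, 4, 5, 6), c(10, 11, 12, 13))
  expect_equal(w$p_less, 1 / choose(10, 4), tolerance = 1e-12)
  expect_equal(w$method, "exact")

  # identical singleton multisets: no separation, two-sided p = 1
  w2 <- wilcoxon_rank_sum(3, 3)
  expect_equal(w2$p_two_sided, 1)

  set.seed(41)
  for (i in 1:30) {
    n1 <- sample(3:6, 1); n2 <- sample(3:6, 1)
    x <- rnorm(n1); y <- rnorm(n2)  # continuous, no ties
    got <- wilcoxon_rank_sum(x, y)
    ref <- wilcox.test(x, y, exact = TRUE)
    expect_equal(got$p_two_sided, unname(ref$p.value), tolerance = 1e-10)
    refl <- wilcox.test(x, y, alternative = "less", exact = TRUE)
    expect_equal(got$p_less, unname(refl$p.value), tolerance = 1e-10)
  }

  # normal-approximation path agrees with wilcox.test(correct = TRUE)
  set.seed(42)
  x <- rnorm(10); y <- rnorm(8, 1)
  got <- wilcoxon_rank_sum(x, y)
  expect_equal(got$method, "normal")
  ref <- wilcox.test(x, y, exact = FALSE, correct = TRUE)
  expect_equal(got$p_two_sided, unname(ref$p.value), tolerance = 1e-8)
})

test_that("compare_group_counts reports mu, sem, fold ratio and exact p", {
  man <- data.frame(sample_id = c(paste0("h", 1:6), paste0("s", 1:4)),
                    group = c(rep("HC", 6), rep("SLE", 4)))
  counts <- setNames(c(109, 527, 527, 527, 527, 1095,
                       1401, 9854, 9855, 47738), man$sample_id)
  cmp <- compare_group_counts(counts, man)
  expect_equal(cmp$mu_control, 552)
  expect_equal(cmp$mu_case, 17212)
  expect_equal(cmp$fold_ratio, 552 / 17212, tolerance = 1e-12)
  expect_equal(cmp$p_one_sided, 1 / 210, tolerance = 1e-12)

  # label symmetry: swapping case/control inverts the ratio, keeps p_two
  cmp2 <- compare_group_counts(counts, man, case = "HC", control = "SLE")
  expect_equal(cmp2$fold_ratio, 1 / cmp$fold_ratio, tolerance = 1e-12)
  expect_equal(cmp2$p_two_sided, cmp$p_two_sided, tolerance = 1e-12)

  expect_error(
    compare_group_counts(counts[c(1, 7, 8)], man[c(1, 7, 8), ]),
    "<2 samples"
  )
})

test_that("length densities integrate to 1 and find mixture modes", {
  man <- data.frame(sample_id = c("a", "b"), group = c("HC", "SLE"))
  single <- circle_catalog(data.frame(chrom = "chr1", start = 0, end = 300,
                                      split_reads = 2), "a", "HC")
  set.seed(43)
  n <- 4000
  lens <- round(c(rnorm(n / 2, 200, 15), rnorm(n / 2, 350, 15)))
  mix <- circle_catalog(data.frame(chrom = "chr1", start = 0, end = lens,
                                   split_reads = 2), "b", "SLE")
  dens <- length_density(list(a = single, b = mix), man, bandwidth = 10,
                         range = c(0, 1000))
  expect_equal(sum(dens$density[, "HC"]), 1, tolerance = 1e-6)
  expect_equal(sum(dens$density[, "SLE"]), 1, tolerance = 1e-6)
  expect_true(all(dens$density >= 0))

  pk_hc <- dens$peaks$length_bp[dens$peaks$group == "HC"]
  expect_length(pk_hc, 1L)
  expect_lt(abs(pk_hc - 300), 3)

  pk_sle <- dens$peaks$length_bp[dens$peaks$group == "SLE"]
  expect_length(pk_sle, 2L)
  expect_lt(abs(pk_sle[1] - 200), 5)
  expect_lt(abs(pk_sle[2] - 350), 5)

  # group with no circles in range is flagged
  man3 <- data.frame(sample_id = c("a", "c"), group = c("HC", "FAR"))
  far <- circle_catalog(data.frame(chrom = "chr1", start = 0, end = 5000,
                                   split_reads = 2), "c", "FAR")
  dens3 <- length_density(list(a = single, c = far), man3, range = c(0, 1000))
  expect_equal(dens3$empty_groups, "FAR")
  expect_true(all(dens3$density[, "FAR"] == 0))
})

test_that("cumulative curves are monotone ECDFs over the range", {
  cat1 <- circle_catalog(data.frame(chrom = "chr1", start = 0,
                                    end = c(100, 200, 300),
                                    split_reads = 2), "s", "G")
  cc <- cumulative_curve(cat1, c(0, 1000))
  expect_true(all(diff(cc$cdf) >= 0))
  expect_equal(cc$cdf[cc$grid == 99], 0)
  expect_equal(cc$cdf[cc$grid == 100], 1 / 3)
  expect_equal(cc$cdf[cc$grid == 300], 1)
  expect_equal(cc$cdf[length(cc$cdf)], 1)

  far <- circle_catalog(data.frame(chrom = "chr1", start = 0, end = 5000,
                                   split_reads = 2), "s", "G")
  cc2 <- cumulative_curve(far, c(0, 1000))
  expect_true(all(cc2$cdf == 0))
  expect_false(cc2$in_range)
})

test_that("rhomboid summaries use sample SD and handle degenerate groups", {
  mk1 <- function(id, grp, ends) {
    circle_catalog(data.frame(chrom = "chr1", start = 0, end = ends,
                              split_reads = 2), id, grp)
  }
  man <- data.frame(sample_id = c("a", "b", "c", "d"),
                    group = c("G1", "G1", "G1", "G2"))
  cats <- list(a = mk1("a", "G1", 150), b = mk1("b", "G1", 250),
               c = mk1("c", "G1", 350), d = mk1("d", "G2", c(100, 300)))
  expect_warning(rs <- rhomboid_summary(cats, man), "single sample")
  g1 <- rs[rs$group == "G1", ]
  expect_equal(g1$count_mu, 1)
  expect_equal(g1$count_sigma, 0)  # counts {1,1,1}
  g2 <- rs[rs$group == "G2", ]
  expect_equal(g2$length_mu, 200)
  expect_equal(g2$length_sigma, sqrt(2 * 100^2 / 1), tolerance = 1e-12)
  expect_equal(g2$count_sigma, 0)  # degenerate single-sample group
  expect_true(all(rs$length_lo <= rs$length_mid & rs$length_mid <= rs$length_hi))
})
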