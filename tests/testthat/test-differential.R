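test_that("all-or-nothing genes follow the degenerate zero-variance rule", {
  eq <- rbind(
    SEP6 = c(rep(0, 6), rep(6, 4)),  # separated by 6 log2 units
    SEP3 = c(rep(0, 6), rep(3, 4)),  # perfectly separated but under theta
    FLAT = rep(2, 10)
  )
  colnames(eq) <- c(paste0("HC", 1:6), paste0("SLE", 1:4))
  mat <- make_ppgc_equalized(eq, c(rep("HC", 6), rep("SLE", 4)))
  sel <- select_dppgc(mat)
  expect_equal(sel$gene, "SEP6")
  expect_equal(sel$diff, 6)
  expect_equal(sel$p_value, 0)
  expect_equal(sel$direction, "up_in_case")
  expect_true(sel$specific_case)
  expect_false(sel$specific_control)

  all_genes <- attr(sel, "all_genes")
  expect_equal(all_genes$p_value[all_genes$gene == "FLAT"], 1)
})

test_that("selection requires both the fold-change gate and significance", {
  set.seed(31)
  eq <- rbind(
    BIGDIFF_NOISY = c(rnorm(6, 0, 4), rnorm(4, 8, 4)),  # large diff, weak p
    SMALL_TIGHT = c(rnorm(6, 0, 0.01), rnorm(4, 1, 0.01))  # tiny diff, strong p
  )
  eq <- pmax(eq, 0)
  colnames(eq) <- paste0("s", 1:10)
  mat <- make_ppgc_equalized(eq, c(rep("HC", 6), rep("SLE", 4)))
  sel <- select_dppgc(mat, pipeline_params(theta_dppgc = 5, alpha_dppgc = 1e-6))
  expect_false("BIGDIFF_NOISY" %in% sel$gene)  # fails alpha
  expect_false("SMALL_TIGHT" %in% sel$gene)    # fails theta
})

test_that("records are ordered by p, then |diff|, then gene", {
  eq <- rbind(
    B = c(rep(0, 6), rep(6, 4)),
    A = c(rep(0, 6), rep(6, 4)),
    C = c(rep(0, 6), rep(7, 4))
  )
  colnames(eq) <- paste0("s", 1:10)
  mat <- make_ppgc_equalized(eq, c(rep("HC", 6), rep("SLE", 4)))
  sel <- select_dppgc(mat)
  # all three have p = 0; C has the largest |diff|; A before B by symbol
  expect_equal(sel$gene, c("C", "A", "B"))
})

test_that("t statistic and p agree with the textbook formula and t.test", {
  set.seed(32)
  for (i in 1:30) {
    x1 <- rnorm(4, sample(0:6, 1)); x0 <- rnorm(6)
    eq <- matrix(pmax(c(x0, x1), 0), nrow = 1,
                 dimnames = list("G", paste0("s", 1:10)))
    mat <- make_ppgc_equalized(eq, c(rep("HC", 6), rep("SLE", 4)))
    tab <- attr(select_dppgc(mat), "all_genes")
    ref <- ttest_textbook(eq[1, 7:10], eq[1, 1:6])
    expect_equal(tab$t, ref$t, tolerance = 1e-10)
    expect_equal(tab$p_value, ref$p, tolerance = 1e-10)
    ref2 <- t.test(eq[1, 7:10], eq[1, 1:6], var.equal = TRUE)
    expect_equal(tab$p_value, unname(ref2$p.value), tolerance = 1e-10)
  }
})

test_that("selection is monotone in theta", {
  set.seed(33)
  eq <- matrix(pmax(rnorm(200 * 10, 3, 3), 0), nrow = 200,
               dimnames = list(sprintf("G%03d", 1:200), paste0("s", 1:10)))
  eq[1:10, 7:10] <- eq[1:10, 7:10] + 8
  mat <- make_ppgc_equalized(eq, c(rep("HC", 6), rep("SLE", 4)))
  prev <- NULL
  for (theta in c(0, 2, 5, 8, 12)) {
    sel <- select_dppgc(mat, pipeline_params(theta_dppgc = theta))$gene
    if (!is.null(prev)) expect_true(all(sel %in% prev))
    prev <- sel
  }
})

test_that("specificity flags require presence in all of one group only", {
  raw <- rbind(
    SPEC = c(rep(0, 6), 2, 3, 4, 2),
    GAP = c(rep(0, 6), 2, 3, 0, 2),
    LEAK = c(0, 1, 0, 0, 0, 0, 2, 3, 4, 2),
    CTRL = c(rep(1, 6), rep(0, 4))
  )
  colnames(raw) <- paste0("s", 1:10)
  mat <- make_ppgc(raw, c(rep("HC", 6), rep("SLE", 4)))
  fl <- specificity_flags(mat)
  expect_equal(fl$specific_case, c(TRUE, FALSE, FALSE, FALSE))
  expect_equal(fl$specific_control, c(FALSE, FALSE, FALSE, TRUE))
  expect_false(any(fl$specific_case & fl$specific_control))
})

test_that("case-specific genes above theta are always selected", {
  # degenerate-variance rule guarantees significance for all-or-nothing genes
  set.seed(34)
  for (i in 1:20) {
    v <- runif(4, 5, 12)
    eq <- matrix(c(rep(0, 6), v), nrow = 1,
                 dimnames = list("G", paste0("s", 1:10)))
    mat <- make_ppgc_equalized(eq, c(rep("HC", 6), rep("SLE", 4)))
    sel <- select_dppgc(mat)
    if (mean(v) >= 5) expect_equal(sel$gene, "G")
  }
})

test_that("differential selection needs two samples per group", {
  eq <- matrix(1:6, nrow = 2, dimnames = list(c("A", "B"), paste0("s", 1:3)))
  mat <- make_ppgc_equalized(eq, c("HC", "SLE", "SLE"))
  expect_error(select_dppgc(mat), "<2 samples")
})

test_that("fragment_vs_whole labels selected genes by up-group carriage", {
  eq <- rbind(FRAG = c(rep(0, 4), rep(6, 2)),
              WHOLE = c(rep(0, 4), rep(7, 2)))
  colnames(eq) <- paste0("s", 1:6)
  groups <- c(rep("HC", 4), rep("SLE", 2))
  mat <- make_ppgc_equalized(eq, groups)
  sel <- select_dppgc(mat)
  whole_report <- list(per_sample = list(
    s1 = character(), s2 = character(), s3 = "WHOLE", s4 = character(),
    s5 = "WHOLE", s6 = character()
  ))
  fw <- fragment_vs_whole_summary(sel, whole_report, mat$samples)
  expect_equal(fw$carriage[fw$gene == "FRAG"], "fragment_only")
  # WHOLE is carried in case sample s5 -> whole_carried
  expect_equal(fw$carriage[fw$gene == "WHOLE"], "whole_carried")

  empty <- sel[0, ]
  attr(empty, "case") <- "SLE"; attr(empty, "control") <- "HC"
  expect_equal(nrow(fragment_vs_whole_summary(empty, whole_report, mat$samples)), 0L)
})

test_that("planted case-specific genes are recovered on a synthetic cohort", {
  res <- small_cohort(2024, count_mean = c(control = 150, case = 150),
                      n_genes = 120, n_planted = 4)
  core <- pipeline_core(res)
  sel <- core$dppgc
  expect_setequal(sel$gene[sel$specific_case & sel$direction == "up_in_case"],
                  res$truth$planted_genes)
  planted_rows <- sel[sel$gene %in% res$truth$planted_genes, ]
  expect_true(all(planted_rows$diff >= 8))
})
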