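genes2 <- gene_annotation(data.frame(
  chrom = "chr1", start = c(0, 2050), end = c(2000, 3000),
  name = c("A", "B")
))

mk <- function(start, end, sr = 2, chrom = "chr1", sample = "s1", group = "HC") {
  circle_catalog(data.frame(chrom = chrom, start = start, end = end,
                            split_reads = sr), sample, group)
}

test_that("annotate_circles uses half-open overlap semantics", {
  a <- annotate_circles(mk(150, 250), genes2)
  expect_equal(a$gene, "A")

  both <- annotate_circles(mk(1990, 2100), genes2)
  expect_setequal(both$gene, c("A", "B"))

  # half-open abutment is no overlap
  none <- annotate_circles(mk(2000, 2050), genes2)
  expect_equal(nrow(none), 0L)
  expect_equal(attr(none, "n_unassigned"), 1L)

  expect_message(annotate_circles(mk(10, 20, chrom = "chr9"), genes2),
                 "absent from annotation")
})

test_that("annotate_circles agrees with the all-pairs overlap oracle", {
  set.seed(21)
  for (i in 1:20) {
    nc <- sample(5:60, 1); ng <- sample(5:60, 1)
    cat1 <- random_catalog(nc, maxpos = 800)
    gs <- sample.int(800, ng, replace = TRUE)
    ann <- gene_annotation(data.frame(
      chrom = sample(c("chr1", "chr2"), ng, replace = TRUE),
      start = gs, end = gs + sample.int(80, ng, replace = TRUE),
      name = sprintf("G%03d", seq_len(ng))
    ))
    got <- annotate_circles(cat1, ann)
    want <- brute_overlap(as.data.frame(cat1), as.data.frame(ann))
    want_df <- data.frame(circle = want$circle, gene = ann$name[want$gene_row])
    want_df <- want_df[order(want_df$circle, want_df$gene), ]
    expect_equal(got$circle, want_df$circle)
    expect_equal(got$gene, want_df$gene)
  }
})

test_that("compute_ppgc sums, scales by L_Max/L_i and log2-equalizes", {
  cat1 <- mk(c(10, 50), c(200, 400), sr = c(3, 2))
  man <- data.frame(sample_id = "s1", group = "HC")
  a <- annotate_circles(cat1, gene_annotation(data.frame(
    chrom = "chr1", start = 0, end = 2000, name = "A")))
  m <- compute_ppgc(list(s1 = a), man)
  expect_equal(unname(m$raw["A", "s1"]), 5)

  # worked scaling example: A len 2000 raw 3, B len 1000 raw 3
  ann <- gene_annotation(data.frame(chrom = "chr1", start = c(0, 3000),
                                    end = c(2000, 4000), name = c("A", "B")))
  cat2 <- mk(c(100, 3100), c(200, 3200), sr = c(3, 3))
  m2 <- compute_ppgc(list(s1 = annotate_circles(cat2, ann)), man)
  expect_equal(m2$l_max, 2000)
  expect_equal(unname(m2$scaled[c("A", "B"), "s1"]), c(3, 6))
  expect_equal(unname(m2$equalized[c("A", "B"), "s1"]), c(2, log2(7)))
})

test_that("compute_ppgc drops all-zero genes and errors without genic circles", {
  ann <- gene_annotation(data.frame(chrom = "chr1", start = 0, end = 100,
                                    name = "A"))
  man <- data.frame(sample_id = "s1", group = "HC")
  a_empty <- annotate_circles(mk(5000, 5100), ann)
  expect_error(compute_ppgc(list(s1 = a_empty), man), "no genic eccDNA")

  # zero raw in one sample -> equalized 0 there
  man2 <- data.frame(sample_id = c("s1", "s2"), group = c("HC", "SLE"))
  a1 <- annotate_circles(mk(10, 60, sr = 4), ann)
  a2 <- annotate_circles(mk(5000, 5100, sample = "s2"), ann)
  m <- compute_ppgc(list(s1 = a1, s2 = a2), man2)
  expect_equal(unname(m$equalized["A", "s2"]), 0)
})

test_that("ppgc invariants: scaled >= raw, equalized monotone in raw", {
  set.seed(22)
  res <- small_cohort(104, n_genes = 50, n_planted = 2)
  core <- pipeline_core(res)
  m <- core$ppgc
  expect_true(all(m$scaled >= m$raw))
  expect_true(all((m$equalized == 0) == (m$raw == 0)))
  # monotone: within each gene, ordering by raw implies ordering by equalized
  for (g in sample(rownames(m$raw), 10)) {
    o <- order(m$raw[g, ])
    expect_true(all(diff(m$equalized[g, o]) >= 0))
  }
  # gene attaining l_max is unscaled
  top <- names(which(m$gene_lengths == m$l_max))[1]
  expect_equal(m$scaled[top, ], m$raw[top, ])
})

test_that("proportional attribution never exceeds full attribution", {
  res <- small_cohort(105, n_genes = 40, n_planted = 2)
  man <- read_manifest(res$paths$manifest)
  genes <- read_gene_bed(res$paths$gene_bed)
  filtered <- lapply(read_catalogs(man), filter_chain)
  asn <- lapply(filtered, annotate_circles, genes = genes)
  full <- compute_ppgc(asn, man, attribution = "full")
  prop <- compute_ppgc(asn, man, attribution = "proportional")
  common <- intersect(rownames(full$raw), rownames(prop$raw))
  expect_true(all(prop$raw[common, ] <= full$raw[common, ] + 1e-9))
})

test_that("whole_gene_carriage detects containment and recurrence", {
  ann <- gene_annotation(data.frame(chrom = "chr1", start = 100, end = 200,
                                    name = "G1"))
  contained <- mk(90, 250, sample = "s1")
  fragment <- mk(150, 400, sample = "s2")
  contained3 <- mk(80, 300, sample = "s3")
  rep1 <- whole_gene_carriage(list(s1 = contained, s2 = fragment,
                                   s3 = contained3), ann)
  expect_equal(rep1$per_sample$s1, "G1")
  expect_equal(rep1$per_sample$s2, character())
  expect_equal(rep1$recurrent$gene, "G1")
  expect_equal(rep1$recurrent$N, 2L)
  expect_equal(rep1$recurrent$L, 100L)
  expect_equal(rep1$recurrent$samples, "s1,s3")

  # containment implies overlap: whole-carried genes appear in assignments
  asn <- annotate_circles(contained, ann)
  expect_true(all(rep1$per_sample$s1 %in% asn$gene))
})
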