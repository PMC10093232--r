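# eccdiff

Gene-level differential analysis of extrachromosomal circular DNA
(eccDNA) from split-read circle calls.

## What it does, and for whom

Circle callers (Circle_finder and kin) report, per sample, a BED-like
table of eccDNA intervals with the number of junction-spanning split
reads supporting each circle. Global summaries of such data — circle
counts, length spectra — often fail to separate sample groups,
especially for cell-free eccDNA from plasma. `eccdiff` is for
bioinformaticians who want the gene-resolved view: it cleans and merges
per-sample catalogs, quantifies circle production per gene, and tests
every gene for differential production between two groups.

The pipeline, with all defaults matching the published method it
implements:

1. **Filter chain** — drop mitochondrial circles and circles longer than
   `l_max` = 10 kb; single-linkage merge of circles whose breakpoints
   both lie within `d_min` = 10 bp (split reads summed, best-supported
   coordinates kept); drop circles with fewer than `jt_min` = 2 split
   reads.
2. **PpGC quantification** — per gene *i* and sample, sum the split
   reads of every overlapping circle (produced-per-gene circles), scale
   by `L_Max / L_i` (longest detected gene over gene length), equalize
   as `log2(PpGC + 1)`.
3. **DPpGC selection** — select genes with
   `|mean_case − mean_control| ≥ θ` (= 5 log2 units) **and** equal-
   variance Student's t-test `p ≤ α` (= 0.01); flag group-specific genes
   (nonzero in all case samples, zero in all controls) and label
   selected genes fragment-only vs whole-gene-carried.
4. **Global statistics** — exact Wilcoxon rank-sum comparison of
   per-sample unique-circle counts with fold ratio, smoothed length
   densities with local-maxima calling, cumulative length curves,
   rhomboid (µ ± σ) vertices.
5. **Enrichment** — hypergeometric over-representation of the selected
   genes against GMT gene-set collections (background = assayed genes),
   plus plain gene-list intersection.
6. **Synthetic cohorts** — a seeded generator emulating the two-group
   structure (≈31× count difference, nucleosomal length peaks at 200 and
   350 bp, planted case-specific genes, filter-exercising noise), so the
   full pipeline is testable without controlled-access data.

## Worked example

```r
library(eccdiff)

cfg <- synth_config(seed = 7, n_genes = 80, n_planted = 3)
res <- generate_cohort(cfg, "demo_cohort")
out <- run_pipeline(run_config(res$paths$manifest, res$paths$gene_bed,
                               outdir = "demo_out", verbose = FALSE))
out$ppgc
#> ppgc_matrix: 80 genes x 10 samples (groups: HC n=6, SLE n=4), L_Max = 19960 bp
out$dppgc
#> dppgc: 35 selected genes (case SLE vs control HC); 10 case-specific
#>         gene mean_case mean_control      diff         t      p_value  direction
#> 1  GENE_0034  9.289873    0.0000000  9.289873 951.71315 1.664009e-21 up_in_case
#> 2  GENE_0003  8.729831    0.0000000  8.729831 778.27216 8.320423e-21 up_in_case
#> 3  GENE_0074 12.378708    0.0000000 12.378708 624.93089 4.814266e-20 up_in_case
#> ...
res$truth$planted_genes
#> [1] "GENE_0003" "GENE_0034" "GENE_0074"
```

The three planted case-specific genes top the ranking (they are
all-or-nothing genes: huge mean difference in log2 units, tiny pooled
variance). The remaining selected genes are driven by the ~31× group
difference in circle abundance that the default cohort profile
emulates — real differences, not false positives, mirroring how the
case group's higher circle load produces many genuinely up-produced
genes. The global count comparison on the same run:

```r
as.data.frame(out$count_comparison)[c("mu_control", "mu_case", "fold_ratio", "p_one_sided")]
#>   mu_control mu_case fold_ratio p_one_sided
#> 1   36.66667 1205.25 0.03042246 0.004761905
```

With 6 controls below 4 cases the exact one-sided rank-sum p is
`1/C(10,4) = 0.00476`, and the fold ratio is ~0.03 (controls produce
~30× fewer circles). The smoothed length densities recover the
nucleosomal peaks in both groups:

```r
subset(out$length_summary$peaks, density > 0.002)
#>    group length_bp     density
#> 1     HC       200 0.013637887
#> 2     HC       352 0.007396676
#> 12   SLE       199 0.011026935
#> 13   SLE       350 0.007540131
```

Every table is also written to `demo_out/` as deterministic TSV
(`dppgc.tsv`, `ppgc_{raw,scaled,equalized}.tsv`, `sample_counts.tsv`,
`length_density.tsv`, `rhomboid_vertices.tsv`, ...), alongside a
`run_manifest.json` with parameters, `L_Max`, and input checksums.

## Command line

```sh
inst/cli/eccdiff run -c config.yaml          # full pipeline from a YAML config
inst/cli/eccdiff simulate --seed 1 --out dir # synthetic cohort
inst/cli/eccdiff filter --in calls.tsv --out filtered.tsv
inst/cli/eccdiff quantify --manifest m.tsv --genes genes.bed --out dir
inst/cli/eccdiff diff --matrix-dir dir --manifest m.tsv --out dppgc.tsv
inst/cli/eccdiff lengths --manifest m.tsv --out dir
inst/cli/eccdiff enrich --signal s.txt --background b.txt --gmt sets.gmt --out e.tsv
```

Stage-wise subcommands compose to the same results as the monolithic
run (tested).

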