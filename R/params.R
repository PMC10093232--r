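#' Pipeline parameters
#'
#' Bundles the tunable constants of the catalog-cleaning chain and the
#' differential selection. Defaults are the published method's values:
#' circles longer than `l_max` = 10 kb are discarded, circles whose two
#' breakpoints both lie within `d_min` = 10 bp of another circle's are
#' merged, merged circles with fewer than `jt_min` = 2 junction-supporting
#' split reads are dropped, and a gene is called differential when the
#' group-mean difference of log2-equalized PpGC is at least `theta_dppgc`
#' = 5 (log2 units, i.e. a 5-fold change in log2 scale) with a Student's
#' t-test p-value at or below `alpha_dppgc` = 0.01.
#'
#' @param l_max maximum circle length retained (bp). Strict: length >
#'   `l_max` is removed, length == `l_max` kept.
#' @param d_min merge distance (bp). Circles link when both |delta start|
#'   and |delta end| are strictly below `d_min`.
#' @param jt_min minimum split reads; circles with fewer are removed after
#'   merging.
#' @param mito_names chromosome aliases treated as mitochondrial.
#' @param theta_dppgc fold-change selection threshold in log2 units.
#' @param alpha_dppgc t-test significance level for DPpGC selection.
#' @param alpha_wilcoxon significance level for the group circle-count
#'   comparison.
#' @return a `pipeline_params` list.
#' @export
pipeline_params <- function(l_max = 10000,
                            d_min = 10,
                            jt_min = 2,
                            mito_names = c("chrM", "chrMT", "MT", "M"),
                            theta_dppgc = 5,
                            alpha_dppgc = 0.01,
                            alpha_wilcoxon = 0.01) {
  stopifnot(
    l_max > 0, d_min >= 0, jt_min >= 1,
    theta_dppgc >= 0,
    alpha_dppgc > 0, alpha_dppgc < 1,
    alpha_wilcoxon > 0, alpha_wilcoxon < 1
  )
  structure(
    list(
      l_max = l_max, d_min = d_min, jt_min = jt_min,
      mito_names = as.character(mito_names),
      theta_dppgc = theta_dppgc, alpha_dppgc = alpha_dppgc,
      alpha_wilcoxon = alpha_wilcoxon
    ),
    class = "pipeline_params"
  )
}

#' @export
print.pipeline_params <- function(x, ...) {
  cat(sprintf(
    "pipeline_params: l_max=%g bp, d_min=%g bp, jt_min=%g, theta=%g log2, alpha=%g\n",
    x$l_max, x$d_min, x$jt_min, x$theta_dppgc, x$alpha_dppgc
  ))
  invisible(x)
}
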