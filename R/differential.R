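#' Select differentially produced per-gene circles (DPpGC)
#'
#' For every gene the group means of the log2-equalized PpGC values are
#' compared: a gene is selected when |mean(case) - mean(control)| >=
#' `theta_dppgc` AND the two-sided equal-variance Student's t-test
#' (pooled variance, df = n1 + n2 - 2) gives p <= `alpha_dppgc`.
#'
#' All-or-nothing genes have zero pooled variance; with unequal means their
#' fold change is infinite and they are treated as maximally significant
#' (t = Inf, p = 0, ranked first), mirroring how infinite-FC genes top the
#' published rankings. Zero variance with equal means gives p = 1.
#'
#' @param mat a `ppgc_matrix` from [compute_ppgc()].
#' @param params a [pipeline_params()] (uses `theta_dppgc`, `alpha_dppgc`).
#' @param case,control group labels; default: the alphabetically second
#'   label is the case group.
#' @param alternative `"two.sided"` (default) or one-sided
#'   `"greater"`/`"less"` on diff = mean(case) - mean(control).
#' @param bh apply Benjamini-Hochberg adjustment to the p-values before the
#'   alpha gate (off by default; the selection level is a raw alpha).
#' @return a `dppgc` data.frame ordered by ascending p, then descending
#'   |diff|, then gene: columns `gene`, `mean_case`, `mean_control`,
#'   `diff`, `t`, `p_value`, `direction`, `specific_case`,
#'   `specific_control`. Attributes `case`/`control` record the labels;
#'   attribute `all_genes` holds the unselected full table.
#' @export
select_dppgc <- function(mat, params = pipeline_params(),
                         case = NULL, control = NULL,
                         alternative = c("two.sided", "greater", "less"),
                         bh = FALSE) {
  alternative <- match.arg(alternative)
  labs <- resolve_groups(mat$samples$group, case, control)
  i_case <- which(mat$samples$group == labs["case"])
  i_ctrl <- which(mat$samples$group == labs["control"])
  if (length(i_case) < 2L || length(i_ctrl) < 2L) {
    stop("group with <2 samples: differential testing needs >= 2 per group")
  }
  x1 <- mat$equalized[, i_case, drop = FALSE]
  x0 <- mat$equalized[, i_ctrl, drop = FALSE]
  n1 <- ncol(x1); n0 <- ncol(x0)
  m1 <- rowMeans(x1); m0 <- rowMeans(x0)
  diff <- m1 - m0
  ss <- rowSums((x1 - m1)^2) + rowSums((x0 - m0)^2)
  df <- n1 + n0 - 2L
  s2p <- ss / df
  se <- sqrt(s2p * (1 / n1 + 1 / n0))
  t <- ifelse(se > 0, diff / se, ifelse(diff == 0, 0, sign(diff) * Inf))
  p <- switch(alternative,
    two.sided = 2 * stats::pt(-abs(t), df),
    greater = stats::pt(t, df, lower.tail = FALSE),
    less = stats::pt(t, df)
  )
  # degenerate zero-variance genes: p = 0 when separated, p = 1 when flat
  p[se == 0] <- ifelse(diff[se == 0] == 0, 1, 0)
  if (bh) p <- stats::p.adjust(p, method = "BH")
  flags <- specificity_flags(mat, case = labs["case"], control = labs["control"])
  tab <- data.frame(
    gene = rownames(mat$equalized),
    mean_case = m1, mean_control = m0, diff = diff, t = t, p_value = p,
    direction = ifelse(diff >= 0, "up_in_case", "up_in_control"),
    specific_case = flags$specific_case,
    specific_control = flags$specific_control,
    stringsAsFactors = FALSE
  )
  rownames(tab) <- NULL
  sel <- tab[abs(tab$diff) >= params$theta_dppgc & tab$p_value <= params$alpha_dppgc, ,
             drop = FALSE]
  sel <- sel[order(sel$p_value, -abs(sel$diff), sel$gene), , drop = FALSE]
  rownames(sel) <- NULL
  structure(sel,
    case = unname(labs["case"]), control = unname(labs["control"]),
    all_genes = tab, class = c("dppgc", "data.frame")
  )
}

#' @export
print.dppgc <- function(x, ...) {
  cat(sprintf(
    "dppgc: %d selected genes (case %s vs control %s); %d case-specific\n",
    nrow(x), attr(x, "case"), attr(x, "control"), sum(x$specific_case)
  ))
  if (nrow(x) > 0L) print(utils::head(as.data.frame(x), 10L))
  invisible(x)
}

#' Group-specificity flags per gene
#'
#' A gene is case-specific when its unscaled PpGC is positive in every
#' case sample and zero in every control sample; control-specific is the
#' mirror image. The two flags are mutually exclusive.
#'
#' @inheritParams select_dppgc
#' @return data.frame `gene`, `specific_case`, `specific_control`.
#' @export
specificity_flags <- function(mat, case = NULL, control = NULL) {
  labs <- resolve_groups(mat$samples$group, case, control)
  r1 <- mat$raw[, mat$samples$group == labs["case"], drop = FALSE]
  r0 <- mat$raw[, mat$samples$group == labs["control"], drop = FALSE]
  data.frame(
    gene = rownames(mat$raw),
    specific_case = apply(r1, 1, min) > 0 & apply(r0, 1, max) == 0,
    specific_control = apply(r0, 1, min) > 0 & apply(r1, 1, max) == 0,
    row.names = NULL, stringsAsFactors = FALSE
  )
}

#' Fragment-only versus whole-gene labels for selected genes
#'
#' Labels every selected gene `fragment_only` when it is never
#' whole-carried by a circle in any sample of its up group, otherwise
#' `whole_carried`.
#'
#' @param records a `dppgc` from [select_dppgc()].
#' @param whole_report output of [whole_gene_carriage()] computed on the
#'   same catalogs.
#' @param samples data.frame `sample_id`, `group` (e.g. `mat$samples`).
#' @return data.frame `gene`, `direction`, `carriage`.
#' @export
fragment_vs_whole_summary <- function(records, whole_report, samples) {
  if (nrow(records) == 0L) {
    return(data.frame(gene = character(), direction = character(),
                      carriage = character(), stringsAsFactors = FALSE))
  }
  up_group <- ifelse(records$direction == "up_in_case",
                     attr(records, "case"), attr(records, "control"))
  carried <- vapply(seq_len(nrow(records)), function(i) {
    ids <- samples$sample_id[samples$group == up_group[i]]
    any(vapply(whole_report$per_sample[ids],
               function(v) records$gene[i] %in% v, NA))
  }, NA)
  data.frame(
    gene = records$gene, direction = records$direction,
    carriage = ifelse(carried, "whole_carried", "fragment_only"),
    stringsAsFactors = FALSE
  )
}

# pick case/control labels; default control = alphabetically first group
resolve_groups <- function(groups, case = NULL, control = NULL) {
  levels <- sort(unique(groups))
  if (length(levels) != 2L) stop("need exactly two group labels, found: ",
                                 paste(levels, collapse = ", "))
  if (is.null(case) && is.null(control)) {
    control <- levels[1L]; case <- levels[2L]
  } else if (is.null(case)) {
    case <- setdiff(levels, control)
  } else if (is.null(control)) {
    control <- setdiff(levels, case)
  }
  if (!all(c(case, control) %in% levels) || isTRUE(case == control)) {
    stop("case/control labels must name the two manifest groups")
  }
  c(case = unname(case), control = unname(control))
}
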