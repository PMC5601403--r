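# Cohort-level PDUI statistics: the directional shift between group mean
# PDUIs, a variance contrast between two cohorts (gray- vs white-matter-like
# behaviour), and the variability-quartile analysis relating within-control
# PDUI spread to between-group PDUI differences.

group_means_by_gene <- function(mat, groups, level) {
  cols <- names(groups)[groups == level]
  cols <- intersect(cols, colnames(mat))
  rowMeans(mat[, cols, drop = FALSE], na.rm = TRUE)
}

#' One-sided KS test on per-gene group mean PDUIs
#'
#' For every gene the mean PDUI is computed within each of the two groups;
#' the two resulting distributions of gene-level means are compared with a
#' one-sided two-sample Kolmogorov-Smirnov test. `direction = "greater"`
#' tests whether the second group's means are stochastically greater than
#' the first group's (a distal shift in group B), `"less"` the opposite.
#'
#' @param mat genes-by-samples PDUI matrix (typically restricted to
#'   significant genes); missing values allowed.
#' @param groups named vector mapping sample ids to two group labels; the
#'   first sorted level is "A", the second "B".
#' @param direction `"greater"` (B > A) or `"less"` (B < A).
#' @return list with `statistic` (D) and `p.value`.
#' @export
ks_group_shift <- function(mat, groups, direction = c("greater", "less")) {
  direction <- match.arg(direction)
  lv <- sort(unique(as.character(groups)))
  if (length(lv) != 2L) stop("exactly two groups required")
  groups <- stats::setNames(as.character(groups), names(groups))
  mA <- group_means_by_gene(mat, groups, lv[1])
  mB <- group_means_by_gene(mat, groups, lv[2])
  keep <- is.finite(mA) & is.finite(mB)
  if (any(!keep)) warning(sum(!keep), " gene(s) with all-missing PDUI in a group excluded")
  mA <- mA[keep]; mB <- mB[keep]
  if (length(mA) < 3L) stop("at least 3 genes required for the KS shift test")
  # R's ks.test alternative refers to the CDF of x: "less" means the CDF of
  # x lies below that of y, i.e. x stochastically greater.
  alt <- if (direction == "greater") "less" else "greater"
  kt <- suppressWarnings(stats::ks.test(mB, mA, alternative = alt))
  list(statistic = unname(kt$statistic), p.value = kt$p.value)
}

# Wilcoxon rank-sum policy used throughout: exact when both sides have at
# most 25 observations and there are no ties, tie-corrected normal
# approximation otherwise. A fully tied input (zero rank variance) is a
# degenerate case reported as no dominance (p = 0.5).
rank_sum_greater <- function(x, y) {
  if (length(unique(c(x, y))) == 1L)
    return(list(statistic = length(x) * length(y) / 2, p.value = 0.5))
  exact <- length(x) <= 25L && length(y) <= 25L && !any(duplicated(c(x, y)))
  wt <- suppressWarnings(stats::wilcox.test(x, y, alternative = "greater",
                                            exact = exact, correct = TRUE))
  list(statistic = unname(wt$statistic), p.value = wt$p.value)
}

row_variances <- function(mat) {
  v <- apply(mat, 1L, function(r) {
    r <- r[!is.na(r)]
    if (length(r) < 2L) NA_real_ else stats::var(r)
  })
  v[!is.na(v)]
}

#' One-sided variance contrast between two PDUI matrices
#'
#' Computes the per-gene across-sample PDUI variance in each matrix and
#' tests, with an unpaired one-sided Wilcoxon rank-sum test, whether the
#' variances of `mat1` stochastically dominate those of `mat2` (e.g. gray
#' matter vs white matter).
#'
#' @param mat1,mat2 genes-by-samples PDUI matrices; genes need at least 2
#'   non-missing samples to contribute a variance.
#' @return list with `statistic` (W) and `p.value`.
#' @export
variance_contrast <- function(mat1, mat2) {
  v1 <- row_variances(mat1)
  v2 <- row_variances(mat2)
  if (length(v1) < 3L || length(v2) < 3L)
    stop("at least 3 per-gene variances required in each matrix")
  rank_sum_greater(v1, v2)
}

#' Variability-quartile analysis of PDUI
#'
#' Per gene, the standard deviation of PDUI within the control group and
#' the absolute difference of group mean PDUIs are computed. Genes are
#' ranked by the absolute mean difference; the control SDs of the top 25%
#' are compared against those of the bottom 25% with an unpaired one-sided
#' Wilcoxon rank-sum test (alternative: top > bottom). Quartiles are rank
#' cuts of size `floor(n/4)`, ties broken by gene id for determinism.
#'
#' @param mat genes-by-samples PDUI matrix.
#' @param groups named vector mapping sample ids to two group labels.
#' @param control the label of the control group.
#' @return list with `statistic`, `p.value` and `table`, a data.frame of
#'   per-gene `control_sd`, `abs_mean_diff` and quartile membership.
#' @export
variability_quartiles <- function(mat, groups, control) {
  groups <- stats::setNames(as.character(groups), names(groups))
  lv <- unique(groups)
  if (!control %in% lv) stop("control label not found in groups")
  other <- setdiff(lv, control)
  if (length(other) != 1L) stop("exactly two groups required")
  ctrl_cols <- intersect(names(groups)[groups == control], colnames(mat))
  ctrl_sd <- apply(mat[, ctrl_cols, drop = FALSE], 1L, function(r) {
    r <- r[!is.na(r)]
    if (length(r) < 2L) NA_real_ else stats::sd(r)
  })
  mC <- group_means_by_gene(mat, groups, control)
  mO <- group_means_by_gene(mat, groups, other)
  tab <- data.frame(gene_id = rownames(mat), control_sd = ctrl_sd,
                    abs_mean_diff = abs(mO - mC), stringsAsFactors = FALSE)
  tab <- tab[stats::complete.cases(tab), , drop = FALSE]
  n <- nrow(tab)
  if (n < 8L) stop("at least 8 genes required so that quartiles are non-empty")
  q <- floor(n / 4)
  if (q < 1L) stop("quartile boundaries produce empty groups")
  tab <- tab[order(-tab$abs_mean_diff, tab$gene_id), , drop = FALSE]
  tab$quartile <- "middle"
  tab$quartile[seq_len(q)] <- "top"
  tab$quartile[seq.int(n - q + 1L, n)] <- "bottom"
  res <- rank_sum_greater(tab$control_sd[tab$quartile == "top"],
                          tab$control_sd[tab$quartile == "bottom"])
  rownames(tab) <- NULL
  list(statistic = res$statistic, p.value = res$p.value, table = tab)
}
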