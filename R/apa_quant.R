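# The core two-site APA model. Coverage over a 3' UTR is modelled as a step
# function: both isoforms cover the region upstream of the proximal
# cleavage site, only the distal (long) isoform covers the region
# downstream. A single shared breakpoint is fitted across all samples of a
# gene by exhaustive search, and per-sample isoform weights give the PDUI
# (Percentage Distal poly(A) site Usage Index): the fraction of the gene's
# transcript output attributable to the long isoform.

#' Fit the two-site (change-point) APA model for one gene
#'
#' For each candidate breakpoint `b` (number of proximal bases, i.e. the
#' 0-based index of the first distal-only position), the expected coverage
#' is `w_long + w_short` upstream of `b` and `w_long` downstream. Weights
#' are fitted per sample in closed form under non-negativity:
#' `w_long = max(0, mean(c[i >= b]))`, `w_short = max(0, mean(c[i < b]) -
#' w_long)`. The shared breakpoint minimises the sum over samples of the
#' step-model squared error, each sample's error normalised by its total
#' coverage; ties go to the smallest `b` (shortest proximal UTR).
#'
#' Samples with mean coverage below `min_mean_coverage` are excluded from
#' the fit. When `groups` is supplied and fewer than 2 samples per group
#' survive, the gene is returned with status `"insufficient_coverage"`.
#'
#' @param tracks samples-by-positions numeric matrix, or a named list of
#'   equal-length coverage vectors (one per sample), transcript orientation.
#' @param groups optional named vector mapping sample ids to two group
#'   labels; used only for the coverage-survival precondition.
#' @param min_mean_coverage per-sample mean-coverage threshold (default 30).
#' @param edge_margin breakpoints closer than this to either UTR end are not
#'   considered; default `max(10, ceiling(0.01 * L))`.
#' @param gene_id identifier carried into the result.
#' @return object of class `apa_fit`: a list with `gene_id`, `status`
#'   (`"ok"` or `"insufficient_coverage"`), `breakpoint` (distance in nt
#'   from the UTR 5' start), `utr_length`, `fit_sse` (normalised SSE at the
#'   chosen breakpoint) and `samples`, a data.frame of per-sample
#'   `w_long`, `w_short`, `pdui` (`NA` when `w_long + w_short == 0`),
#'   `mean_coverage` and `used`.
#' @export
fit_two_site_model <- function(tracks, groups = NULL, min_mean_coverage = 30,
                               edge_margin = NULL, gene_id = NA_character_) {
  if (is.list(tracks)) {
    lens <- vapply(tracks, length, integer(1))
    if (length(unique(lens)) != 1L) stop("validation error: tracks of unequal length")
    mat <- do.call(rbind, lapply(tracks, as.numeric))
    if (!is.null(names(tracks))) rownames(mat) <- names(tracks)
  } else {
    mat <- as.matrix(tracks)
  }
  if (is.null(rownames(mat))) rownames(mat) <- paste0("sample", seq_len(nrow(mat)))
  if (nrow(mat) < 1L) stop("at least one track required")
  if (anyNA(mat) || any(mat < 0)) stop("validation error: negative or missing coverage")
  L <- ncol(mat)
  if (is.null(edge_margin)) edge_margin <- max(10L, ceiling(0.01 * L))
  if (2L * edge_margin >= L) stop("UTR too short for edge margin ", edge_margin)

  mean_cov <- rowMeans(mat)
  used <- mean_cov >= min_mean_coverage
  insufficient <- if (!is.null(groups)) {
    g <- as.character(groups[rownames(mat)])
    any(vapply(unique(g), function(gl) sum(used & g == gl) < 2L, logical(1)))
  } else {
    !any(used)
  }
  samples_df <- data.frame(
    sample_id = rownames(mat), w_long = NA_real_, w_short = NA_real_,
    pdui = NA_real_, mean_coverage = mean_cov, used = used,
    stringsAsFactors = FALSE, row.names = NULL
  )
  if (insufficient) {
    return(structure(list(gene_id = gene_id, status = "insufficient_coverage",
                          breakpoint = NA_integer_, utr_length = L,
                          fit_sse = NA_real_, samples = samples_df),
                     class = "apa_fit"))
  }

  # candidate breakpoints: b proximal bases, b in [edge_margin, L - edge_margin)
  b_cand <- seq.int(edge_margin, L - edge_margin - 1L)
  total_sse <- numeric(length(b_cand))
  for (s in which(used)) {
    c_s <- mat[s, ]
    S <- cumsum(c_s); S2 <- cumsum(c_s^2)
    Tot <- S[L]; Tot2 <- S2[L]
    if (Tot == 0) next
    Sp <- S[b_cand]; S2p <- S2[b_cand]
    mp <- Sp / b_cand
    md <- (Tot - Sp) / (L - b_cand)
    wl <- pmax(0, md)
    ws <- pmax(0, mp - wl)
    lev_p <- wl + ws
    sse <- (S2p - 2 * lev_p * Sp + b_cand * lev_p^2) +
      ((Tot2 - S2p) - 2 * wl * (Tot - Sp) + (L - b_cand) * wl^2)
    total_sse <- total_sse + sse / Tot
  }
  best <- which.min(total_sse) # ties -> smallest b
  b <- b_cand[best]

  prox <- seq_len(b); dist <- (b + 1L):L
  for (s in seq_len(nrow(mat))) {
    wl <- max(0, mean(mat[s, dist]))
    ws <- max(0, mean(mat[s, prox]) - wl)
    samples_df$w_long[s] <- wl
    samples_df$w_short[s] <- ws
    samples_df$pdui[s] <- if (wl + ws > 0) wl / (wl + ws) else NA_real_
  }
  structure(list(gene_id = gene_id, status = "ok", breakpoint = b,
                 utr_length = L, fit_sse = total_sse[best],
                 samples = samples_df),
            class = "apa_fit")
}

#' @export
print.apa_fit <- function(x, ...) {
  cat("Two-site APA fit for", x$gene_id, "- status:", x$status, "\n")
  if (x$status == "ok")
    cat("  breakpoint:", x$breakpoint, "of", x$utr_length, "nt; mean PDUI:",
        round(mean(x$samples$pdui[x$samples$used], na.rm = TRUE), 3), "\n")
  invisible(x)
}

#' Assemble a PDUI matrix from per-gene fits
#'
#' @param fits list of `apa_fit` objects. Genes with status other than
#'   `"ok"` are skipped. PDUI values of samples excluded from the fit are
#'   set to `NA`.
#' @return genes-by-samples numeric matrix of PDUI values.
#' @export
pdui_matrix <- function(fits) {
  ok <- Filter(function(f) f$status == "ok", fits)
  if (length(ok) == 0L) stop("no genes with a successful fit")
  samples <- ok[[1L]]$samples$sample_id
  m <- t(vapply(ok, function(f) {
    v <- ifelse(f$samples$used, f$samples$pdui, NA_real_)
    v[match(samples, f$samples$sample_id)]
  }, numeric(length(samples))))
  dimnames(m) <- list(vapply(ok, function(f) f$gene_id, character(1)), samples)
  m
}

#' Differential APA testing between two groups
#'
#' Per gene, a 2x2 contingency table of isoform-attributable read mass is
#' built by summing, over each group's contributing samples,
#' `w_long * (L - b)` (long-isoform mass) and `w_short * b` (short-isoform
#' mass), rounding to integers. A two-sided Fisher exact test is applied,
#' p-values are Benjamini-Hochberg adjusted across all tested genes, and a
#' gene is flagged significant when `adj_p < alpha` and the absolute group
#' PDUI difference exceeds `min_diff`.
#'
#' @param fits list of `apa_fit` objects (one per gene).
#' @param groups named vector mapping sample ids to exactly two group
#'   labels; the PDUI difference is reported as second group minus first
#'   (group levels sorted unless `groups` is a factor).
#' @param alpha significance level on the adjusted p-value (default 0.05).
#' @param min_diff minimum absolute group PDUI difference (default 0.2).
#' @return data.frame of class `differential_apa_table`: `gene_id`,
#'   `mean_pdui_A`/`mean_pdui_B` (first/second group level), `pdui_diff`
#'   (B - A), `p_value`, `adj_p`, `significant`; ordered by gene id. Genes
#'   with fewer than 2 defined PDUIs per group are excluded.
#' @export
differential_apa <- function(fits, groups, alpha = 0.05, min_diff = 0.2) {
  lv <- if (is.factor(groups)) levels(groups) else sort(unique(as.character(groups)))
  if (length(lv) != 2L) stop("exactly two groups required")
  groups <- stats::setNames(as.character(groups), names(groups))
  rows <- list()
  for (f in fits) {
    if (f$status != "ok") next
    sm <- f$samples[f$samples$used & !is.na(f$samples$pdui), , drop = FALSE]
    g <- groups[sm$sample_id]
    if (sum(g == lv[1], na.rm = TRUE) < 2L || sum(g == lv[2], na.rm = TRUE) < 2L) next
    b <- f$breakpoint; L <- f$utr_length
    mass <- function(gl) {
      sel <- which(g == gl)
      c(long = round(sum(sm$w_long[sel]) * (L - b)),
        short = round(sum(sm$w_short[sel]) * b))
    }
    tab <- rbind(mass(lv[1]), mass(lv[2]))
    p <- if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) 1
         else stats::fisher.test(tab)$p.value
    mA <- mean(sm$pdui[g == lv[1]])
    mB <- mean(sm$pdui[g == lv[2]])
    rows[[length(rows) + 1L]] <- data.frame(
      gene_id = f$gene_id, mean_pdui_A = mA, mean_pdui_B = mB,
      pdui_diff = mB - mA, p_value = p, stringsAsFactors = FALSE
    )
  }
  if (length(rows) == 0L) {
    res <- data.frame(gene_id = character(), mean_pdui_A = numeric(),
                      mean_pdui_B = numeric(), pdui_diff = numeric(),
                      p_value = numeric(), adj_p = numeric(),
                      significant = logical(), stringsAsFactors = FALSE)
    class(res) <- c("differential_apa_table", "data.frame")
    return(res)
  }
  res <- do.call(rbind, rows)
  res$adj_p <- benjamini_hochberg(res$p_value)
  res$significant <- res$adj_p < alpha & abs(res$pdui_diff) > min_diff
  res <- res[order(res$gene_id), , drop = FALSE]
  rownames(res) <- NULL
  class(res) <- c("differential_apa_table", "data.frame")
  res
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Thin validated front-end to `stats::p.adjust(method = "BH")`; output
#' order matches input order.
#'
#' @param p_values numeric vector of p-values in \[0, 1\].
#' @return adjusted p-values.
#' @export
benjamini_hochberg <- function(p_values) {
  if (anyNA(p_values) || any(p_values < 0 | p_values > 1))
    stop("validation error: p-values must lie in [0, 1]")
  stats::p.adjust(p_values, method = "BH")
}
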