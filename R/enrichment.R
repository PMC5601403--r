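# Gene-list meta-analysis: expressed-background definition from TPM,
# hypergeometric overlap tests, length-bias-aware category enrichment (a
# GOseq-style test with an isotonic probability-weighting function),
# PDUI-input gene-set enrichment with the unweighted KS running-sum score,
# and promoter motif scanning.

#' TPM from raw counts
#'
#' Per sample: `rate_g = count_g / length_g`, `TPM_g = 1e6 * rate_g /
#' sum(rates)`. A sample with zero total counts yields an all-zero column
#' with a warning.
#'
#' @param counts genes-by-samples matrix of raw counts.
#' @param lengths positive gene lengths in nt, one per row of `counts`.
#' @return TPM matrix of the same shape.
#' @export
tpm_from_counts <- function(counts, lengths) {
  counts <- as.matrix(counts)
  if (length(lengths) != nrow(counts)) stop("one length per gene required")
  if (any(lengths <= 0)) stop("gene lengths must be positive")
  rate <- counts / lengths
  tot <- colSums(rate)
  zero <- tot == 0
  if (any(zero)) {
    warning(sum(zero), " sample(s) with zero counts: TPM column set to 0")
    tot[zero] <- 1
  }
  sweep(rate, 2L, tot, "/") * 1e6
}

#' Expressed-gene background from a TPM matrix
#'
#' Genes whose across-sample median TPM is strictly greater than
#' `threshold` are considered expressed.
#'
#' @param tpm genes-by-samples TPM matrix with gene rownames.
#' @param threshold median-TPM cut (default 1, strict `>`).
#' @return character vector of expressed gene ids.
#' @export
expressed_background <- function(tpm, threshold = 1) {
  if (ncol(tpm) < 1L) stop("at least one sample required")
  med <- apply(tpm, 1L, stats::median)
  rownames(tpm)[med > threshold]
}

#' Hypergeometric overlap test between two gene lists
#'
#' Upper-tail probability of observing at least the seen overlap between
#' `list_a` and `list_b` when `list_b` is drawn uniformly from the
#' universe. Members outside the universe are dropped with a warning.
#'
#' @param list_a,list_b character vectors of gene ids.
#' @param universe character vector defining the background.
#' @param set_name label carried into the result.
#' @return one-row data.frame: `set`, `overlap`, `expected`, `p_value`,
#'   `adj_p` (equal to `p_value` for a single test), `direction`.
#' @export
hypergeom_overlap <- function(list_a, list_b, universe, set_name = "overlap") {
  universe <- unique(universe)
  if (length(universe) == 0L) stop("empty universe")
  a <- unique(list_a); b <- unique(list_b)
  if (!all(a %in% universe) || !all(b %in% universe)) {
    warning("members outside the universe dropped")
    a <- intersect(a, universe); b <- intersect(b, universe)
  }
  k <- length(intersect(a, b))
  p <- stats::phyper(k - 1, length(a), length(universe) - length(a),
                     length(b), lower.tail = FALSE)
  expected <- length(a) * length(b) / length(universe)
  data.frame(set = set_name, overlap = k, expected = expected, p_value = p,
             adj_p = p, direction = if (k >= expected) "over" else "under",
             stringsAsFactors = FALSE)
}

#' Isotonic probability-weighting function for length bias
#'
#' Estimates, by isotonic (monotone non-decreasing) regression of the hit
#' indicator on gene length, the probability that a gene of a given length
#' is called a hit. Used to de-bias category enrichment for the selection
#' bias between long and short genes in RNA-seq.
#'
#' @param hits character vector of hit gene ids.
#' @param universe character vector of background gene ids.
#' @param lengths named numeric vector of gene lengths covering the
#'   universe.
#' @return named numeric vector of per-gene weights over the universe.
#' @export
length_pwf <- function(hits, universe, lengths) {
  universe <- unique(universe)
  if (!all(universe %in% names(lengths))) stop("every universe gene needs a length_weight")
  len <- lengths[universe]
  y <- as.numeric(universe %in% hits)
  o <- order(len, universe)
  fit <- stats::isoreg(seq_along(o), y[o])$yf
  w <- numeric(length(universe))
  w[o] <- fit
  # average fitted values within tied lengths so the PWF is a function of length
  w <- stats::ave(w, len, FUN = mean)
  w <- pmax(w, 1e-8)
  stats::setNames(w, universe)
}

#' Length-bias-aware category enrichment
#'
#' Tests each category for over-representation among hit genes while
#' correcting for the tendency of long genes to be called hits. The null
#' distribution of the per-category overlap is obtained either by weighted
#' resampling without replacement (weights from [length_pwf()]) or by a
#' Wallenius non-central hypergeometric approximation with category odds
#' derived from the mean weight inside vs outside the category.
#'
#' @param hits character vector of hit gene ids (subset of universe).
#' @param categories named list of character vectors.
#' @param universe background gene ids.
#' @param lengths named numeric lengths covering the universe.
#' @param method `"resampling"` or `"wallenius"`.
#' @param n_resamples resamples for the resampling method (default 10000).
#' @return data.frame: `set`, `size` (category genes in universe),
#'   `overlap`, `p_value`, `adj_p` (BH across categories), `direction`.
#'   Categories with no universe member are skipped.
#' @export
length_aware_enrichment <- function(hits, categories, universe, lengths,
                                    method = c("resampling", "wallenius"),
                                    n_resamples = 10000L) {
  method <- match.arg(method)
  universe <- unique(universe)
  hits <- intersect(unique(hits), universe)
  if (method == "resampling" && n_resamples < 1L)
    stop("n_resamples must be >= 1 for the resampling method")
  w <- length_pwf(hits, universe, lengths)
  n_hits <- length(hits)
  cats <- lapply(categories, function(m) intersect(unique(m), universe))
  keep <- vapply(cats, length, integer(1)) >= 1L
  cats <- cats[keep]
  if (length(cats) == 0L) stop("no category overlaps the universe")
  obs <- vapply(cats, function(m) length(intersect(m, hits)), integer(1))

  if (method == "resampling") {
    in_cat <- vapply(cats, function(m) universe %in% m, logical(length(universe)))
    exceed <- integer(length(cats))
    for (r in seq_len(n_resamples)) {
      draw <- sample.int(length(universe), n_hits, replace = FALSE, prob = w)
      cnt <- colSums(in_cat[draw, , drop = FALSE])
      exceed <- exceed + (cnt >= obs)
    }
    p <- (1 + exceed) / (1 + n_resamples)
  } else {
    p <- vapply(seq_along(cats), function(i) {
      m1 <- length(cats[[i]])
      inside <- universe %in% cats[[i]]
      odds <- mean(w[inside]) / mean(w[!inside])
      wallenius_upper(obs[i], m1, length(universe) - m1, n_hits, odds)
    }, numeric(1))
  }
  res <- data.frame(
    set = names(cats), size = vapply(cats, length, integer(1)),
    overlap = obs, p_value = p, stringsAsFactors = FALSE
  )
  res$adj_p <- benjamini_hochberg(res$p_value)
  res$direction <- ifelse(res$overlap >= n_hits * res$size / length(universe),
                          "over", "under")
  rownames(res) <- NULL
  res
}

# Upper-tail P(X >= k) of the Wallenius non-central hypergeometric
# distribution with m1 "category" balls, m2 others, n draws, odds w,
# evaluated by the standard one-dimensional integral representation of the
# mass function.
wallenius_upper <- function(k, m1, m2, n, w) {
  support <- max(0L, n - m2):min(n, m1)
  dens <- vapply(support, function(x) {
    D <- w * (m1 - x) + (m2 - (n - x))
    if (D <= 0) return(0)
    f <- function(t) {
      lg <- x * log1p(-t^(w / D)) + (n - x) * log1p(-t^(1 / D))
      exp(lg)
    }
    I <- tryCatch(stats::integrate(f, 0, 1, rel.tol = 1e-10)$value,
                  error = function(e) NA_real_)
    if (is.na(I)) return(NA_real_)
    exp(lchoose(m1, x) + lchoose(m2, n - x) + log(I))
  }, numeric(1))
  if (anyNA(dens)) return(NA_real_)
  dens <- dens / sum(dens) # guard numerical drift
  sum(dens[support >= k])
}

#' Unweighted KS running-sum enrichment score
#'
#' Walks a ranked gene list adding `1/Nh` at set members and subtracting
#' `1/(N - Nh)` elsewhere; the score is the running-sum value of maximum
#' absolute deviation from zero (signed), bounded in \[-1, 1\].
#'
#' @param ranked character vector of gene ids, best-ranked first.
#' @param set character vector of member gene ids.
#' @return enrichment score.
#' @export
gsea_enrichment_score <- function(ranked, set) {
  hit <- ranked %in% set
  nh <- sum(hit)
  N <- length(ranked)
  if (nh == 0L || nh == N) stop("set must contain some but not all ranked genes")
  step <- ifelse(hit, 1 / nh, -1 / (N - nh))
  running <- cumsum(step)
  running[which.max(abs(running))]
}

#' PDUI-input gene-set enrichment analysis
#'
#' Genes are scored by the difference of group mean PDUIs (second group
#' minus first; optionally a signal-to-noise ratio), ranked decreasingly,
#' and each gene set is scored with the unweighted KS running-sum statistic.
#' Significance is assessed by phenotype-label permutation when at least 7
#' samples are available, otherwise by gene-set (random member) permutation;
#' the FDR q-value follows the standard normalised-enrichment-score
#' procedure.
#'
#' @param mat genes-by-samples PDUI matrix; genes missing in more than 50%
#'   of samples are excluded.
#' @param groups named vector mapping sample ids to two group labels.
#' @param gene_sets named list of character vectors.
#' @param min_size minimum number of ranked genes a set must contain to be
#'   tested (default 10).
#' @param n_perms number of permutations (default 1000).
#' @param stat `"mean_diff"` (default; stable for very small groups) or
#'   `"snr"` (signal-to-noise with SD floors of 0.01).
#' @return data.frame: `set`, `size`, `es`, `nes`, `p_value`, `fdr_q`,
#'   `enriched_group`. Empty (with a warning) when no set passes
#'   `min_size`.
#' @export
gsea_pdui <- function(mat, groups, gene_sets, min_size = 10L,
                      n_perms = 1000L, stat = c("mean_diff", "snr")) {
  stat <- match.arg(stat)
  lv <- sort(unique(as.character(groups)))
  if (length(lv) != 2L) stop("exactly two groups required")
  groups <- stats::setNames(as.character(groups), names(groups))
  keep <- rowMeans(is.na(mat)) <= 0.5
  mat <- mat[keep, , drop = FALSE]

  score_fun <- function(glabels) {
    a <- mat[, names(glabels)[glabels == lv[1]], drop = FALSE]
    b <- mat[, names(glabels)[glabels == lv[2]], drop = FALSE]
    mA <- rowMeans(a, na.rm = TRUE); mB <- rowMeans(b, na.rm = TRUE)
    if (stat == "mean_diff") return(mB - mA)
    sA <- pmax(apply(a, 1L, stats::sd, na.rm = TRUE), 0.01)
    sB <- pmax(apply(b, 1L, stats::sd, na.rm = TRUE), 0.01)
    (mB - mA) / (sA + sB)
  }
  rank_genes <- function(scores) names(sort(scores, decreasing = TRUE))

  scores <- score_fun(groups)
  names(scores) <- rownames(mat)
  ranked <- rank_genes(scores)
  sets <- lapply(gene_sets, function(m) intersect(unique(m), ranked))
  sizes <- vapply(sets, length, integer(1))
  sets <- sets[sizes >= min_size & sizes < length(ranked)]
  if (length(sets) == 0L) {
    warning("no gene set passes min_size = ", min_size)
    return(data.frame(set = character(), size = integer(), es = numeric(),
                      nes = numeric(), p_value = numeric(), fdr_q = numeric(),
                      enriched_group = character(), stringsAsFactors = FALSE))
  }
  es_obs <- vapply(sets, function(m) gsea_enrichment_score(ranked, m), numeric(1))

  phenotype_mode <- length(groups) >= 7L
  es_perm <- matrix(NA_real_, nrow = n_perms, ncol = length(sets))
  for (r in seq_len(n_perms)) {
    if (phenotype_mode) {
      gp <- stats::setNames(sample(groups), names(groups))
      rk <- rank_genes(stats::setNames(score_fun(gp), rownames(mat)))
      es_perm[r, ] <- vapply(sets, function(m) gsea_enrichment_score(rk, m),
                             numeric(1))
    } else {
      es_perm[r, ] <- vapply(lengths(sets), function(sz) {
        gsea_enrichment_score(ranked, sample(ranked, sz))
      }, numeric(1))
    }
  }
  if (!phenotype_mode)
    message("fewer than 7 samples: falling back to gene-set permutation")

  norm_side <- function(es, perm) {
    same <- if (es >= 0) perm[perm >= 0] else -perm[perm < 0]
    if (length(same) == 0L) return(c(p = 1 / (n_perms + 1), nes = sign(es)))
    p <- (1 + sum(same >= abs(es))) / (1 + length(same))
    nes <- abs(es) / mean(same) * sign(es)
    c(p = p, nes = nes)
  }
  pn <- t(vapply(seq_along(sets), function(i) norm_side(es_obs[i], es_perm[, i]),
                 c(p = 0, nes = 0)))
  nes_obs <- pn[, "nes"]
  nes_perm <- es_perm
  for (i in seq_along(sets)) {
    pos <- es_perm[, i][es_perm[, i] >= 0]
    neg <- -es_perm[, i][es_perm[, i] < 0]
    mp <- if (length(pos)) mean(pos) else 1
    mn <- if (length(neg)) mean(neg) else 1
    nes_perm[, i] <- ifelse(es_perm[, i] >= 0, es_perm[, i] / mp,
                            es_perm[, i] / mn)
  }
  all_perm <- as.vector(nes_perm)
  fdr <- vapply(nes_obs, function(ns) {
    if (ns >= 0) {
      num <- mean(all_perm >= ns & all_perm >= 0) /
        max(mean(all_perm >= 0), 1e-12)
      den <- mean(nes_obs >= ns & nes_obs >= 0) /
        max(mean(nes_obs >= 0), 1e-12)
    } else {
      num <- mean(all_perm <= ns & all_perm < 0) /
        max(mean(all_perm < 0), 1e-12)
      den <- mean(nes_obs <= ns & nes_obs < 0) /
        max(mean(nes_obs < 0), 1e-12)
    }
    min(1, num / max(den, 1e-12))
  }, numeric(1))

  res <- data.frame(
    set = names(sets), size = lengths(sets), es = es_obs, nes = nes_obs,
    p_value = pn[, "p"], fdr_q = fdr,
    enriched_group = ifelse(es_obs >= 0, lv[2], lv[1]),
    stringsAsFactors = FALSE
  )
  rownames(res) <- NULL
  res[order(res$p_value, res$set), , drop = FALSE]
}

#' Scan sequences for an IUPAC motif
#'
#' Exact IUPAC-expanded matches of the motif, reported as 0-based start
#' positions on the forward strand. With `both_strands = TRUE`,
#' reverse-complement matches are mapped back to forward coordinates; a
#' position matching on both strands (as with the palindromic CRE consensus
#' TGACGTCA) is counted once.
#'
#' @param sequences named character vector of DNA sequences (or a
#'   `Biostrings::DNAStringSet`).
#' @param motif IUPAC motif string (default the CRE consensus `TGACGTCA`).
#' @param both_strands also scan the reverse complement (default TRUE).
#' @return named list of sorted integer vectors of 0-based hit positions.
#' @export
scan_motif <- function(sequences, motif = "TGACGTCA", both_strands = TRUE) {
  if (!nzchar(motif)) stop("motif must be non-empty")
  pat <- tryCatch(Biostrings::DNAString(motif),
                  error = function(e) stop("invalid IUPAC code in motif: ", motif))
  rc <- Biostrings::reverseComplement(pat)
  seq_names <- names(sequences)
  if (!inherits(sequences, "DNAStringSet"))
    sequences <- Biostrings::DNAStringSet(toupper(as.character(sequences)))
  res <- lapply(seq_along(sequences), function(i) {
    subj <- sequences[[i]]
    hits <- Biostrings::start(Biostrings::matchPattern(pat, subj, fixed = FALSE)) - 1L
    if (both_strands) {
      rev_hits <- Biostrings::start(Biostrings::matchPattern(rc, subj, fixed = FALSE)) - 1L
      hits <- union(hits, rev_hits)
    }
    sort(unique(as.integer(hits)))
  })
  names(res) <- if (is.null(seq_names)) paste0("seq", seq_along(res)) else seq_names
  res
}

#' Motif-bearing gene enrichment among APA genes
#'
#' Hypergeometric upper-tail test of whether genes carrying at least one
#' motif occurrence (e.g. the CRE element in their promoter) are
#' over-represented among genes with significant APA events, relative to an
#' expressed-gene universe.
#'
#' @param hit_genes gene ids with at least one motif occurrence.
#' @param apa_genes gene ids with significant APA events.
#' @param universe background gene ids.
#' @return one-row data.frame as from [hypergeom_overlap()].
#' @export
motif_enrichment <- function(hit_genes, apa_genes, universe) {
  hypergeom_overlap(hit_genes, apa_genes, universe, set_name = "motif_enrichment")
}
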