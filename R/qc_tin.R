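# Transcript Integrity Number (TIN): an entropy-based 0-100 measure of how
# uniform read coverage is along a transcript, used as a proxy for RNA
# degradation (roughly RIN x 10). Computed here at every base of the
# provided interval (dense-sampling limit of the RSeQC definition).

#' Transcript Integrity Number of a coverage track
#'
#' With per-base coverage `c_i` over `k` positions and `p_i = c_i / sum(c)`,
#' the TIN is `100 * exp(H) / k` where `H = -sum(p_i log p_i)` (taking
#' `0 log 0 = 0`). Uniform coverage gives 100; a single covered base gives
#' `100 / k`; a track with zero total coverage gives 0 by convention.
#'
#' @param track numeric coverage vector (or [coverage_track()]).
#' @return TIN in \[0, 100\].
#' @export
transcript_tin <- function(track) {
  x <- as.numeric(track)
  if (length(x) < 1L) stop("track length must be >= 1")
  if (anyNA(x) || any(x < 0)) stop("validation error: negative or missing coverage")
  total <- sum(x)
  if (total == 0) return(0)
  p <- x[x > 0] / total
  H <- -sum(p * log(p))
  100 * exp(H) / length(x)
}

#' TIN table over a sample-by-gene grid
#'
#' @param tracks nested list: `tracks[[sample_id]][[gene_id]]` is a coverage
#'   vector. All samples must cover the same genes (missing genes get TIN 0).
#' @return numeric matrix, genes in rows, samples in columns.
#' @export
tin_table <- function(tracks) {
  samples <- names(tracks)
  genes <- unique(unlist(lapply(tracks, names)))
  tin <- matrix(0, nrow = length(genes), ncol = length(samples),
                dimnames = list(genes, samples))
  for (s in samples) {
    for (g in names(tracks[[s]])) tin[g, s] <- transcript_tin(tracks[[s]][[g]])
  }
  tin
}

#' Per-sample mean TIN after removal of zeros
#'
#' @param tin genes-by-samples TIN matrix.
#' @return named numeric vector; a sample whose TINs are all zero gets 0.
#' @export
sample_mean_tin <- function(tin) {
  apply(tin, 2L, function(v) {
    nz <- v[v > 0]
    if (length(nz) == 0L) 0 else mean(nz)
  })
}

#' Apply the two TIN quality filters
#'
#' First, samples whose mean TIN (computed after removing zero TINs) falls
#' strictly below `sample_cut` are dropped. Then genes with a TIN strictly
#' below `transcript_cut` in at least one retained sample are dropped.
#'
#' @param tin genes-by-samples TIN matrix (missing entries must be encoded
#'   as 0).
#' @param sample_cut sample-level mean-TIN threshold (default 40).
#' @param transcript_cut per-transcript TIN threshold (default 60).
#' @return list with `samples` (retained sample ids), `genes` (retained gene
#'   ids), and `mean_tin` (per-sample means used for the filter).
#' @export
apply_tin_filters <- function(tin, sample_cut = 40, transcript_cut = 60) {
  if (is.null(dimnames(tin)) || is.null(rownames(tin)) || is.null(colnames(tin)))
    stop("tin matrix must have gene rownames and sample colnames")
  mt <- sample_mean_tin(tin)
  keep_s <- names(mt)[mt >= sample_cut]
  if (length(keep_s) == 0L)
    stop("all samples dropped by the mean-TIN filter (cut ", sample_cut,
         "); review thresholds")
  sub <- tin[, keep_s, drop = FALSE]
  keep_g <- rownames(sub)[apply(sub, 1L, function(v) all(v >= transcript_cut))]
  list(samples = keep_s, genes = keep_g, mean_tin = mt)
}
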