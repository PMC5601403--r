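# Direct poly(A) evidence: reads that end in an untemplated adenosine run
# pinpoint cleavage positions. This module trims terminal A-stretches,
# clusters the templated 3' ends into candidate poly(A) sites, and checks
# predicted proximal sites against those clusters.

#' Trim terminal poly(A) stretches from read sequences
#'
#' The maximal terminal run of A's is removed if and only if its length is
#' at least `min_a`; internal A runs are never touched. Trimming is not
#' guaranteed idempotent: if the remaining sequence itself ends in a run of
#' `min_a` or more A's (templated A's adjacent to the tail), a second call
#' would trim again.
#'
#' @param read_seq character vector of sequences over A, C, G, T, N
#'   (case-insensitive).
#' @param min_a minimum terminal run length to trim (default 3).
#' @return list with `seq` (trimmed sequences) and `tail_len` (length of the
#'   removed run, 0 where no trimming occurred).
#' @export
trim_polya <- function(read_seq, min_a = 3L) {
  seqs <- toupper(as.character(read_seq))
  if (any(grepl("[^ACGTN]", seqs))) stop("validation error: non-nucleotide characters in read sequence")
  tail_len <- integer(length(seqs))
  out <- seqs
  run <- attr(regexpr("A*$", seqs), "match.length")
  trim <- run >= min_a
  tail_len[trim] <- run[trim]
  out[trim] <- substr(seqs[trim], 1L, nchar(seqs[trim]) - run[trim])
  list(seq = out, tail_len = tail_len)
}

#' Cluster A-tailed read ends into poly(A) sites
#'
#' Read 3'-end positions (post tail-trimming) are single-linkage clustered
#' within `cluster_window` nucleotides per (chrom, strand); each cluster
#' becomes a candidate cleavage site positioned at the modal end (ties
#' broken toward the smallest coordinate), with support equal to the number
#' of reads in the cluster. Clusters with fewer than `min_support` reads are
#' discarded. Only reads whose removed tail was at least `min_a` long count
#' as evidence.
#'
#' @param read_ends data.frame with columns `chrom`, `pos` (0-based genomic
#'   coordinate of the templated 3' end), `strand`, `tail_len`.
#' @param cluster_window single-linkage distance in nt (default 10).
#' @param min_support minimum reads per retained site (default 2).
#' @param min_a minimum tail length for a read to be admitted (default 3).
#' @return data.frame with columns `chrom`, `position`, `strand`, `support`,
#'   ordered by chrom, strand, position. Empty input gives zero rows.
#' @export
call_polya_sites <- function(read_ends, cluster_window = 10L, min_support = 2L, min_a = 3L) {
  empty <- data.frame(chrom = character(), position = integer(),
                      strand = character(), support = integer(),
                      stringsAsFactors = FALSE)
  if (is.null(read_ends) || nrow(read_ends) == 0L) return(empty)
  re <- read_ends[read_ends$tail_len >= min_a, , drop = FALSE]
  if (nrow(re) == 0L) return(empty)
  out <- list()
  for (key in unique(paste(re$chrom, re$strand))) {
    grp <- re[paste(re$chrom, re$strand) == key, , drop = FALSE]
    pos <- sort(grp$pos)
    breaks <- c(0L, which(diff(pos) > cluster_window), length(pos))
    for (k in seq_len(length(breaks) - 1L)) {
      cl <- pos[(breaks[k] + 1L):breaks[k + 1L]]
      if (length(cl) < min_support) next
      tab <- table(cl)
      modal <- as.integer(names(tab)[tab == max(tab)])
      out[[length(out) + 1L]] <- data.frame(
        chrom = grp$chrom[1], position = min(modal), strand = grp$strand[1],
        support = length(cl), stringsAsFactors = FALSE
      )
    }
  }
  if (length(out) == 0L) return(empty)
  sites <- do.call(rbind, out)
  sites[order(sites$chrom, sites$strand, sites$position), , drop = FALSE]
}

#' Validate a predicted proximal site against poly(A) evidence
#'
#' A prediction is validated when some called poly(A) site lies within
#' `window` nt of it on the same chromosome and strand. The best site is the
#' nearest one; ties go to higher support, then to the smaller coordinate.
#'
#' @param predicted 0-based genomic position of the predicted cleavage site.
#' @param sites data.frame as returned by [call_polya_sites()].
#' @param window maximum distance in nt (default 50).
#' @param chrom,strand restrict candidate sites; `NULL` uses all rows.
#' @return list with `validated` (logical), `best_site` (one-row data.frame
#'   or NULL) and `distance` (NA when not validated).
#' @export
validate_proximal_site <- function(predicted, sites, window = 50L,
                                   chrom = NULL, strand = NULL) {
  if (!is.null(sites) && nrow(sites) > 0L) {
    if (!is.null(chrom)) sites <- sites[sites$chrom == chrom, , drop = FALSE]
    if (!is.null(strand)) sites <- sites[sites$strand == strand, , drop = FALSE]
  }
  if (is.null(sites) || nrow(sites) == 0L)
    return(list(validated = FALSE, best_site = NULL, distance = NA_real_))
  d <- abs(sites$position - predicted)
  near <- which(d <= window)
  if (length(near) == 0L)
    return(list(validated = FALSE, best_site = NULL, distance = NA_real_))
  cand <- sites[near, , drop = FALSE]
  cand_d <- d[near]
  o <- order(cand_d, -cand$support, cand$position)
  best <- cand[o[1L], , drop = FALSE]
  list(validated = TRUE, best_site = best, distance = cand_d[o[1L]])
}

#' Extract read-end records from a simulator poly(A) FASTA
#'
#' The cohort simulator writes A-tailed reads with their templated 3'-end
#' coordinates in the FASTA header (`chrom=... end=... strand=...`), standing
#' in for the alignment step of a real pipeline. This helper parses those
#' headers and recomputes tail lengths from the sequences via [trim_polya()].
#'
#' @param fasta_path path to the simulator's poly(A)-read FASTA.
#' @param min_a minimum tail length passed to [trim_polya()].
#' @return data.frame with columns `chrom`, `pos`, `strand`, `tail_len`.
#' @export
polya_read_ends <- function(fasta_path, min_a = 3L) {
  con <- open_text(fasta_path)
  on.exit(close(con))
  lines <- readLines(con)
  hdr_idx <- grep("^>", lines)
  if (length(hdr_idx) == 0L)
    return(data.frame(chrom = character(), pos = integer(),
                      strand = character(), tail_len = integer()))
  hdr <- lines[hdr_idx]
  seq_start <- hdr_idx + 1L
  seq_end <- c(hdr_idx[-1L] - 1L, length(lines))
  seqs <- vapply(seq_along(hdr_idx), function(i) {
    paste(lines[seq_start[i]:seq_end[i]], collapse = "")
  }, character(1))
  grab <- function(tag) {
    m <- regmatches(hdr, regexpr(paste0(tag, "=[^ ]+"), hdr))
    sub(paste0(tag, "="), "", m)
  }
  trimmed <- trim_polya(seqs, min_a = min_a)
  data.frame(
    chrom = grab("chrom"),
    pos = as.integer(grab("end")),
    strand = grab("strand"),
    tail_len = trimmed$tail_len,
    stringsAsFactors = FALSE
  )
}

#' Write poly(A) sites as BED6
#'
#' Score column carries the read support.
#'
#' @param sites data.frame from [call_polya_sites()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_polya_bed <- function(sites, path) {
  lines <- sprintf("%s\t%d\t%d\tpolyA_site_%d\t%d\t%s",
                   sites$chrom, sites$position, sites$position + 1L,
                   seq_len(nrow(sites)), sites$support, sites$strand)
  writeLines(lines, path)
  invisible(path)
}
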