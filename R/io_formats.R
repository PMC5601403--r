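# Readers/writers for the standard formats the pipeline touches, and the
# single home for coordinate conventions: all internal coordinates are
# 0-based half-open (bedGraph/BED native), and coverage for minus-strand
# genes is stored 5'->3' in transcript orientation so that a breakpoint
# index always means "distance from the UTR 5' start".

#' Construct a coverage track
#'
#' A coverage track is the per-base read depth of one sample over one gene's
#' 3' UTR, oriented 5' to 3' in transcript coordinates (index 1 is the
#' 5'-most base of the UTR regardless of genomic strand).
#'
#' @param values numeric vector of non-negative per-base coverage.
#' @param gene_id,sample_id identifiers carried as attributes.
#' @return numeric vector of class `coverage_track`.
#' @export
coverage_track <- function(values, gene_id = NA_character_, sample_id = NA_character_) {
  values <- as.numeric(values)
  if (length(values) < 1L) stop("coverage track must have length >= 1")
  if (anyNA(values) || any(values < 0)) stop("coverage values must be non-negative and non-missing")
  structure(values, gene_id = gene_id, sample_id = sample_id, class = "coverage_track")
}

open_text <- function(path) {
  # gzfile() transparently reads both gzip-compressed and plain text
  gzfile(path, open = "rt")
}

#' Read gene models (oriented 3' UTR intervals)
#'
#' Gene models give, per gene, the genomic interval of the annotated longest
#' 3' UTR, the strand, the transcription start position (used for upstream
#' motif windows) and a gene length used for length-bias correction.
#'
#' Supported dialects:
#' \describe{
#'   \item{bed12}{BED with >= 6 columns; the chromStart/chromEnd interval is
#'     taken as the 3' UTR. With 12 columns the summed block sizes give
#'     `length_weight`, otherwise the interval length is used. The TSS
#'     defaults to the 5' end of the interval on the gene's strand.}
#'   \item{tabular}{header line with columns `gene_id`, `chrom`, `strand`,
#'     `utr_start`, `utr_end` and optionally `tss`, `length_weight`. Set
#'     `one_based = TRUE` for 1-based inclusive start coordinates; they are
#'     converted to 0-based half-open on read.}
#' }
#'
#' @param path file path (plain or gzipped).
#' @param format `"bed12"` or `"tabular"`.
#' @param one_based for `tabular` only: input starts are 1-based inclusive.
#' @return data.frame with columns gene_id, chrom, strand, utr_start,
#'   utr_end, tss, length_weight; coordinates 0-based half-open.
#' @export
read_gene_models <- function(path, format = c("bed12", "tabular"), one_based = FALSE) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("gene model file not found: ", path)
  if (format == "bed12") {
    con <- open_text(path)
    on.exit(close(con))
    lines <- readLines(con)
    lines <- lines[!grepl("^(#|track|browser)", lines) & nzchar(trimws(lines))]
    if (length(lines) == 0L) {
      warning("empty gene model file: ", path)
      return(empty_gene_models())
    }
    rows <- lapply(seq_along(lines), function(i) {
      f <- strsplit(trimws(lines[[i]]), "\t| +")[[1]]
      if (length(f) < 6L) stop("malformed BED line ", i, " in ", path, ": fewer than 6 fields")
      start <- suppressWarnings(as.integer(f[2]))
      end <- suppressWarnings(as.integer(f[3]))
      if (is.na(start) || is.na(end)) stop("malformed BED line ", i, " in ", path, ": non-integer coordinates")
      if (start >= end) stop("validation error at BED line ", i, ": utr_start >= utr_end")
      strand <- f[6]
      if (!strand %in% c("+", "-")) stop("malformed BED line ", i, ": strand must be + or -")
      lw <- end - start
      if (length(f) >= 11L) {
        sizes <- suppressWarnings(as.integer(strsplit(f[11], ",")[[1]]))
        if (!anyNA(sizes) && length(sizes) > 0L) lw <- sum(sizes)
      }
      data.frame(
        gene_id = f[4], chrom = f[1], strand = strand,
        utr_start = start, utr_end = end,
        tss = if (strand == "+") start else end,
        length_weight = lw,
        stringsAsFactors = FALSE
      )
    })
    models <- do.call(rbind, rows)
  } else {
    models <- read.delim(path, stringsAsFactors = FALSE)
    need <- c("gene_id", "chrom", "strand", "utr_start", "utr_end")
    miss <- setdiff(need, names(models))
    if (length(miss) > 0L) stop("tabular gene model file lacks columns: ", paste(miss, collapse = ", "))
    if (nrow(models) == 0L) {
      warning("empty gene model file: ", path)
      return(empty_gene_models())
    }
    if (one_based) models$utr_start <- models$utr_start - 1L
    if (is.null(models$tss)) models$tss <- ifelse(models$strand == "+", models$utr_start, models$utr_end)
    if (is.null(models$length_weight)) models$length_weight <- models$utr_end - models$utr_start
    bad <- which(models$utr_start >= models$utr_end)
    if (length(bad) > 0L) stop("validation error: utr_start >= utr_end for gene(s) ", paste(models$gene_id[bad], collapse = ", "))
    if (!all(models$strand %in% c("+", "-"))) stop("strand must be + or -")
    models <- models[, c("gene_id", "chrom", "strand", "utr_start", "utr_end", "tss", "length_weight")]
  }
  if (any(models$length_weight <= 0)) stop("length_weight must be positive")
  rownames(models) <- NULL
  models
}

empty_gene_models <- function() {
  data.frame(
    gene_id = character(), chrom = character(), strand = character(),
    utr_start = integer(), utr_end = integer(), tss = integer(),
    length_weight = integer(), stringsAsFactors = FALSE
  )
}

#' Read per-base coverage for one gene from a bedGraph file
#'
#' Expands bedGraph intervals (0-based half-open) to per-base coverage over
#' the gene's 3' UTR. Positions absent from the file get coverage 0
#' (bedGraph semantics). Minus-strand genes are reversed into transcript
#' orientation.
#'
#' @param path bedGraph file (plain or gzipped).
#' @param model a single gene model row (as from [read_gene_models()]).
#' @param sample_id optional identifier stored on the track; defaults to the
#'   file name without extension.
#' @return a [coverage_track()].
#' @export
read_bedgraph <- function(path, model, sample_id = NULL) {
  tracks <- read_bedgraph_all(path, as.data.frame(as.list(model)), sample_id = sample_id)
  tracks[[1L]]
}

parse_bedgraph <- function(path) {
  if (!file.exists(path)) stop("bedGraph file not found: ", path)
  con <- open_text(path)
  on.exit(close(con))
  lines <- readLines(con)
  lines <- lines[!grepl("^(#|track|browser)", lines) & nzchar(trimws(lines))]
  if (length(lines) == 0L)
    return(data.frame(chrom = character(), start = numeric(), end = numeric(),
                      value = numeric()))
  f <- strsplit(trimws(lines), "\t| +")
  nf <- lengths(f)
  if (any(nf < 4L)) stop("malformed bedGraph line ", which(nf < 4L)[1L], " in ", path)
  m <- matrix(unlist(lapply(f, `[`, 1:4)), ncol = 4L, byrow = TRUE)
  iv <- data.frame(chrom = m[, 1],
                   start = suppressWarnings(as.numeric(m[, 2])),
                   end = suppressWarnings(as.numeric(m[, 3])),
                   value = suppressWarnings(as.numeric(m[, 4])),
                   stringsAsFactors = FALSE)
  bad <- which(!complete.cases(iv))
  if (length(bad) > 0L) stop("malformed bedGraph line ", bad[1L], " in ", path)
  if (any(iv$value < 0))
    stop("validation error: negative coverage at bedGraph line ",
         which(iv$value < 0)[1L], " in ", path)
  iv
}

#' Read coverage for many genes from one bedGraph file
#'
#' Parses the file once and expands per-base coverage for every gene model.
#'
#' @param path bedGraph file (plain or gzipped).
#' @param models gene-model data.frame (as from [read_gene_models()]).
#' @param sample_id identifier stored on each track; defaults to the file
#'   name without extension.
#' @return named list of [coverage_track()] objects, one per gene.
#' @export
read_bedgraph_all <- function(path, models, sample_id = NULL) {
  if (is.null(sample_id))
    sample_id <- sub("\\.(bedgraph|bedGraph|bg)(\\.gz)?$", "", basename(path))
  iv <- parse_bedgraph(path)
  out <- vector("list", nrow(models))
  names(out) <- models$gene_id
  for (g in seq_len(nrow(models))) {
    mod <- models[g, ]
    L <- mod$utr_end - mod$utr_start
    values <- numeric(L)
    sel <- iv$chrom == mod$chrom & iv$end > mod$utr_start & iv$start < mod$utr_end
    if (any(sel)) {
      lo <- pmax(iv$start[sel], mod$utr_start)
      hi <- pmin(iv$end[sel], mod$utr_end)
      lens <- as.integer(hi - lo)
      idx <- sequence(lens, from = as.integer(lo - mod$utr_start + 1L))
      values[idx] <- rep(iv$value[sel], lens)
    }
    if (mod$strand == "-") values <- rev(values)
    out[[g]] <- coverage_track(values, gene_id = mod$gene_id, sample_id = sample_id)
  }
  out
}

#' Write a coverage track for one gene as bedGraph intervals
#'
#' Inverse of [read_bedgraph()]: the track (transcript orientation) is
#' flipped back to genomic order for minus-strand genes and emitted as
#' run-length-compressed intervals; zero-coverage runs are omitted.
#'
#' @param track a [coverage_track()].
#' @param model the gene model row the track belongs to.
#' @param path output file; opened in append mode when `append = TRUE` so
#'   one file can hold many genes.
#' @param append append to an existing file.
#' @return `path`, invisibly.
#' @export
write_bedgraph <- function(track, model, path, append = FALSE) {
  model <- as.list(model)
  values <- as.numeric(track)
  if (length(values) != model$utr_end - model$utr_start)
    stop("track length does not match gene model interval")
  if (model$strand == "-") values <- rev(values)
  r <- rle(values)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths
  keep <- r$values != 0
  lines <- sprintf(
    "%s\t%d\t%d\t%s", model$chrom,
    model$utr_start + starts[keep], model$utr_start + ends[keep],
    format(r$values[keep], trim = TRUE, scientific = FALSE)
  )
  con <- file(path, open = if (append) "at" else "wt")
  on.exit(close(con))
  if (length(lines) > 0L) writeLines(lines, con)
  invisible(path)
}

#' Read gene sets from GMT or one-id-per-line files
#'
#' @param path file path (plain or gzipped).
#' @param format `"gmt"` (name, description, members, tab-separated) or
#'   `"one_per_line"` (one gene id per line; the set is named after the
#'   file).
#' @return named list of character vectors (duplicates collapsed, case
#'   preserved). Sets with zero members are skipped with a warning.
#' @export
read_gene_sets <- function(path, format = c("gmt", "one_per_line")) {
  format <- match.arg(format)
  con <- open_text(path)
  on.exit(close(con))
  lines <- readLines(con)
  lines <- lines[nzchar(trimws(lines))]
  if (format == "one_per_line") {
    name <- sub("\\.(txt|list)(\\.gz)?$", "", basename(path))
    members <- unique(trimws(lines))
    if (length(members) == 0L) {
      warning("gene list ", path, " has no members; skipped")
      return(stats::setNames(list(), character()))
    }
    return(stats::setNames(list(members), name))
  }
  sets <- list()
  for (ln in lines) {
    f <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    members <- unique(f[-(1:2)])
    members <- members[nzchar(members)]
    if (length(f) < 3L || length(members) == 0L) {
      warning("gene set '", f[1], "' has no members; skipped")
      next
    }
    sets[[f[1]]] <- members
  }
  sets
}

#' Write a results table as deterministic TSV
#'
#' Rows are ordered by `gene_id` (when present), floats printed at 6
#' significant digits, so re-running on the same input yields a
#' byte-identical file.
#'
#' @param table a data.frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_results_table <- function(table, path) {
  if (is.null(table)) stop("table must not be NULL")
  table <- as.data.frame(table)
  if ("gene_id" %in% names(table) && nrow(table) > 1L)
    table <- table[order(table$gene_id), , drop = FALSE]
  for (j in seq_along(table)) {
    if (is.double(table[[j]])) {
      table[[j]] <- format(signif(table[[j]], 6), trim = TRUE, scientific = NA)
    }
  }
  ok <- tryCatch({
    write.table(table, path, sep = "\t", quote = FALSE, row.names = FALSE)
    TRUE
  }, error = function(e) stop("cannot write results table to ", path, ": ", conditionMessage(e)))
  invisible(path)
}
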