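# Synthetic cohort generator. Emulates the structure the downstream
# analysis assumes: two phenotype groups, per-gene two-isoform coverage
# mixtures with a group-level PDUI shift, per-gene PDUI variability
# controlled by a Beta concentration (low concentration = gray-matter-like
# variability, high = white-matter-like), 3' degradation bias graded by a
# target TIN, and reads carrying untemplated poly(A) tails at the true
# cleavage sites. Every draw is recorded in a truth table.

#' Simulation configuration
#'
#' Defaults describe a small two-group brain-cohort-like study: 200 genes,
#' 6 samples per group, mean coverage 50 reads/base, a modest distal shift
#' in group B (Beta means 0.4 vs 0.55), moderate between-sample PDUI
#' variability (concentration 20), 10% multiplicative log-normal coverage
#' noise, no degradation bias, and poly(A)-tailed reads emitted at both
#' cleavage sites at a rate of 0.2 per unit depth.
#'
#' @param n_genes number of genes.
#' @param utr_length_range min/max 3' UTR length (nt).
#' @param breakpoint_fraction_range min/max proximal-site position as a
#'   fraction of UTR length, inside (0, 1).
#' @param n_A,n_B samples per group (a warning is issued below 2).
#' @param pdui_means per-group Beta means of the true PDUI, in \[0, 1\].
#' @param pdui_concentration Beta concentration kappa (> 0); smaller means
#'   more between-sample PDUI variability.
#' @param depth_mean expected reads per base.
#' @param depth_dispersion squared coefficient of variation of per-sample
#'   depth (Gamma model; 0 = constant depth).
#' @param degradation_tin_target target TIN in (0, 100] induced by the 5'->3'
#'   decay profile; 100 = no bias.
#' @param polya_read_rate expected A-tailed reads per cleavage site per unit
#'   depth (0 disables read emission).
#' @param noise_sd standard deviation of multiplicative log-normal coverage
#'   noise (0 = noise-free).
#' @param seed root RNG seed; per-gene streams are derived from it by
#'   counter so adding genes never reshuffles existing ones.
#' @return list of class `simulation_config`.
#' @export
simulation_config <- function(n_genes = 200L,
                              utr_length_range = c(300L, 1500L),
                              breakpoint_fraction_range = c(0.3, 0.7),
                              n_A = 6L, n_B = 6L,
                              pdui_means = c(A = 0.4, B = 0.55),
                              pdui_concentration = 20,
                              depth_mean = 50,
                              depth_dispersion = 0.1,
                              degradation_tin_target = 100,
                              polya_read_rate = 0.2,
                              noise_sd = 0.1,
                              seed = 1L) {
  stopifnot(n_genes >= 1, length(utr_length_range) == 2L,
            utr_length_range[1] <= utr_length_range[2])
  if (any(breakpoint_fraction_range <= 0) || any(breakpoint_fraction_range >= 1))
    stop("breakpoint_fraction_range must lie within (0, 1)")
  if (any(pdui_means < 0 | pdui_means > 1)) stop("pdui_means must lie in [0, 1]")
  if (pdui_concentration <= 0) stop("pdui_concentration must be positive")
  if (degradation_tin_target <= 0 || degradation_tin_target > 100)
    stop("degradation_tin_target must lie in (0, 100]")
  if (noise_sd < 0 || depth_dispersion < 0) stop("noise_sd and depth_dispersion must be >= 0")
  if (n_A < 2L || n_B < 2L) warning("fewer than 2 samples in a group: group statistics degenerate")
  structure(list(
    n_genes = as.integer(n_genes), utr_length_range = as.integer(utr_length_range),
    breakpoint_fraction_range = breakpoint_fraction_range,
    n_A = as.integer(n_A), n_B = as.integer(n_B),
    pdui_means = pdui_means, pdui_concentration = pdui_concentration,
    depth_mean = depth_mean, depth_dispersion = depth_dispersion,
    degradation_tin_target = degradation_tin_target,
    polya_read_rate = polya_read_rate, noise_sd = noise_sd,
    seed = as.integer(seed)
  ), class = "simulation_config")
}

#' 5'-to-3' degradation bias profile with a target TIN
#'
#' A one-parameter exponential decay `exp(-r * i / (L - 1))` over the UTR
#' whose decay rate `r` is solved by bisection so that the TIN of the
#' profile itself (via [transcript_tin()]) is within 0.01 of the target.
#' `tin_target = 100` returns a flat (all-ones) profile.
#'
#' @param utr_len UTR length in nt.
#' @param tin_target target TIN in (0, 100].
#' @return positive, monotone non-increasing numeric vector of length
#'   `utr_len`.
#' @export
degradation_profile <- function(utr_len, tin_target) {
  if (tin_target <= 0 || tin_target > 100) stop("tin_target must lie in (0, 100]")
  if (utr_len == 1L || tin_target == 100) return(rep(1, utr_len))
  floor_tin <- 100 / utr_len
  if (tin_target <= floor_tin)
    stop("tin_target unreachable for this family; feasible range is (",
         format(floor_tin, digits = 4), ", 100]")
  x <- seq(0, 1, length.out = utr_len)
  tin_at <- function(r) transcript_tin(exp(-r * x))
  lo <- 0; hi <- 1
  while (tin_at(hi) > tin_target) {
    hi <- hi * 2
    if (hi > 1e8) stop("bisection failed to bracket the target TIN")
  }
  for (i in 1:200) {
    mid <- (lo + hi) / 2
    if (tin_at(mid) > tin_target) lo <- mid else hi <- mid
    if (hi - lo < 1e-12) break
  }
  exp(-((lo + hi) / 2) * x)
}

#' Simulate two-isoform coverage for one gene
#'
#' Expected coverage is `depth` upstream of the breakpoint and
#' `depth * pdui` downstream (the inverse of the two-site model), then
#' multiplied by the bias profile and, when `noise_sd > 0`, by per-base
#' log-normal noise with unit mean, and finally rounded to non-negative
#' integers. Uses the current RNG state; seed before calling for
#' reproducibility.
#'
#' @param utr_len UTR length (nt).
#' @param breakpoint proximal-site position: number of bases upstream of
#'   the cleavage point, strictly inside (0, utr_len).
#' @param pdui true fraction of distal-isoform output, in \[0, 1\].
#' @param depth expected reads per base.
#' @param bias optional non-negative profile of length `utr_len` (default
#'   flat).
#' @param noise_sd log-normal sigma (0 = deterministic).
#' @return a [coverage_track()].
#' @export
simulate_gene_coverage <- function(utr_len, breakpoint, pdui, depth,
                                   bias = NULL, noise_sd = 0) {
  if (pdui < 0 || pdui > 1) stop("validation error: pdui must lie in [0, 1]")
  if (breakpoint <= 0 || breakpoint >= utr_len)
    stop("breakpoint must be strictly inside the UTR")
  if (is.null(bias)) bias <- rep(1, utr_len)
  if (length(bias) != utr_len) stop("bias profile length must equal utr_len")
  expected <- depth * c(rep(1, breakpoint), rep(pdui, utr_len - breakpoint)) * bias
  if (noise_sd > 0)
    expected <- expected * stats::rlnorm(utr_len, meanlog = -noise_sd^2 / 2,
                                         sdlog = noise_sd)
  coverage_track(pmax(0, round(expected)))
}

gene_stream_seed <- function(root_seed, g) {
  as.integer((as.numeric(root_seed) * 48271 + g * 16807) %% 2147483647)
}

random_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                                collapse = "")

#' Simulate a two-group cohort with ground truth
#'
#' Generates per-gene, per-sample coverage tracks from the two-isoform step
#' model, writes per-sample bedGraph files, a BED12 gene-model file, a group
#' table, a truth table recording every latent draw, and (when
#' `polya_read_rate > 0`) a FASTA of fixed-length 50 nt reads ending at the
#' true cleavage sites with 3-10 untemplated A's, whose templated 3'-end
#' coordinates are carried in the headers (see [polya_read_ends()]).
#'
#' Per-gene true PDUIs are drawn from Beta distributions with the group
#' means and shared concentration of the config; per-sample depths from a
#' Gamma with the configured mean and dispersion. Per-gene RNG streams are
#' derived from the root seed by counter, so outputs are byte-identical for
#' a fixed seed and adding genes never reshuffles existing ones.
#'
#' @param config a [simulation_config()].
#' @param out_dir output directory (created); `NULL` keeps everything in
#'   memory only.
#' @return list with `models` (gene-model data.frame), `truth` (per
#'   gene-sample data.frame with `true_breakpoint`, `true_pdui`, `depth`),
#'   `groups` (named vector), `tracks` (nested list sample -> gene ->
#'   coverage), and `paths` (named vector of written files, if any).
#' @export
simulate_cohort <- function(config, out_dir = NULL) {
  stopifnot(inherits(config, "simulation_config"))
  samples <- c(paste0("A", seq_len(config$n_A)), paste0("B", seq_len(config$n_B)))
  groups <- stats::setNames(rep(c("A", "B"), c(config$n_A, config$n_B)), samples)
  gm <- config$pdui_means
  if (is.null(names(gm))) names(gm) <- c("A", "B")
  kappa <- config$pdui_concentration

  genes <- sprintf("gene%04d", seq_len(config$n_genes))
  lens <- integer(config$n_genes)
  bps <- integer(config$n_genes)
  truth <- vector("list", config$n_genes)
  tracks <- lapply(samples, function(s) list())
  names(tracks) <- samples
  reads <- list()

  for (g in seq_len(config$n_genes)) {
    set.seed(gene_stream_seed(config$seed, g))
    len <- as.integer(round(stats::runif(1, config$utr_length_range[1],
                                         config$utr_length_range[2])))
    bf <- stats::runif(1, config$breakpoint_fraction_range[1],
                       config$breakpoint_fraction_range[2])
    b <- min(max(as.integer(round(bf * len)), 1L), len - 1L)
    lens[g] <- len; bps[g] <- b
    bias <- degradation_profile(len, config$degradation_tin_target)

    pduis <- depths <- numeric(length(samples))
    for (si in seq_along(samples)) {
      mu <- gm[[groups[[samples[si]]]]]
      pduis[si] <-
        if (mu == 0 || mu == 1) mu
        else stats::rbeta(1, mu * kappa, (1 - mu) * kappa)
      depths[si] <-
        if (config$depth_dispersion == 0) config$depth_mean
        else stats::rgamma(1, shape = 1 / config$depth_dispersion,
                           scale = config$depth_mean * config$depth_dispersion)
      tracks[[samples[si]]][[genes[g]]] <- simulate_gene_coverage(
        len, b, pduis[si], depths[si], bias = bias, noise_sd = config$noise_sd
      )
      if (config$polya_read_rate > 0) {
        for (site in c("proximal", "distal")) {
          n_reads <- stats::rpois(1, config$polya_read_rate * depths[si])
          for (k in seq_len(n_reads)) {
            tail_n <- sample(3:10, 1)
            reads[[length(reads) + 1L]] <- list(
              gene = genes[g], sample = samples[si], site = site,
              seq = paste0(random_dna(50L - tail_n), strrep("A", tail_n))
            )
          }
        }
      }
    }
    truth[[g]] <- data.frame(
      gene_id = genes[g], sample_id = samples, true_breakpoint = b,
      true_pdui = pduis, depth = depths, stringsAsFactors = FALSE
    )
  }

  # deterministic genomic placement on one chromosome, strands alternating
  starts <- cumsum(c(1000L, head(lens, -1L) + 1000L))
  strands <- rep(c("+", "-"), length.out = config$n_genes)
  models <- data.frame(
    gene_id = genes, chrom = "chrS", strand = strands,
    utr_start = starts, utr_end = starts + lens,
    tss = ifelse(strands == "+", starts, starts + lens),
    length_weight = lens, stringsAsFactors = FALSE
  )
  truth <- do.call(rbind, truth)

  # genomic cleavage coordinates for the A-tailed reads
  if (length(reads) > 0L) {
    idx <- match(vapply(reads, `[[`, character(1), "gene"), models$gene_id)
    site <- vapply(reads, `[[`, character(1), "site")
    pos <- ifelse(
      models$strand[idx] == "+",
      ifelse(site == "proximal", models$utr_start[idx] + bps[idx], models$utr_end[idx]),
      ifelse(site == "proximal", models$utr_end[idx] - bps[idx], models$utr_start[idx])
    )
    read_df <- data.frame(
      name = sprintf("read%06d", seq_along(reads)),
      gene = models$gene_id[idx], chrom = models$chrom[idx],
      end = as.integer(pos), strand = models$strand[idx],
      seq = vapply(reads, `[[`, character(1), "seq"),
      stringsAsFactors = FALSE
    )
  } else read_df <- NULL

  paths <- character()
  if (!is.null(out_dir)) {
    dir.create(file.path(out_dir, "coverage"), recursive = TRUE, showWarnings = FALSE)
    bed <- sprintf("%s\t%d\t%d\t%s\t0\t%s\t%d\t%d\t0\t1\t%d,\t0,",
                   models$chrom, models$utr_start, models$utr_end,
                   models$gene_id, models$strand, models$utr_start,
                   models$utr_end, models$length_weight)
    writeLines(bed, file.path(out_dir, "models.bed"))
    paths["models"] <- file.path(out_dir, "models.bed")
    for (s in samples) {
      p <- file.path(out_dir, "coverage", paste0(s, ".bedgraph"))
      if (file.exists(p)) file.remove(p)
      for (g in seq_len(config$n_genes))
        write_bedgraph(tracks[[s]][[genes[g]]], models[g, ], p, append = TRUE)
      paths[paste0("coverage_", s)] <- p
    }
    write_results_table(truth, file.path(out_dir, "truth.tsv"))
    paths["truth"] <- file.path(out_dir, "truth.tsv")
    writeLines(paste(samples, groups, sep = "\t"), file.path(out_dir, "groups.tsv"))
    paths["groups"] <- file.path(out_dir, "groups.tsv")
    if (!is.null(read_df)) {
      fa <- as.vector(rbind(
        sprintf(">%s gene=%s chrom=%s end=%d strand=%s", read_df$name,
                read_df$gene, read_df$chrom, read_df$end, read_df$strand),
        read_df$seq
      ))
      writeLines(fa, file.path(out_dir, "polya_reads.fasta"))
      paths["polya_reads"] <- file.path(out_dir, "polya_reads.fasta")
    }
  }
  list(models = models, truth = truth, groups = groups, tracks = tracks,
       reads = read_df, paths = paths)
}

#' Simulate a PDUI matrix directly (no coverage)
#'
#' Convenience generator for group-level statistics: per-gene, per-sample
#' PDUIs drawn from group-specific Beta distributions, bypassing the
#' coverage model entirely.
#'
#' @param n_genes number of genes.
#' @param n_A,n_B samples per group.
#' @param means per-group Beta means, length 2 (A then B).
#' @param concentration Beta concentration kappa.
#' @param seed RNG seed.
#' @return list with `matrix` (genes x samples) and `groups`.
#' @export
simulate_pdui_matrix <- function(n_genes, n_A, n_B, means = c(0.5, 0.5),
                                 concentration = 20, seed = 1L) {
  set.seed(seed)
  samples <- c(paste0("A", seq_len(n_A)), paste0("B", seq_len(n_B)))
  groups <- stats::setNames(rep(c("A", "B"), c(n_A, n_B)), samples)
  mu <- rep(means, c(n_A, n_B))
  m <- t(vapply(seq_len(n_genes), function(g) {
    stats::rbeta(length(samples), mu * concentration, (1 - mu) * concentration)
  }, numeric(length(samples))))
  dimnames(m) <- list(sprintf("gene%04d", seq_len(n_genes)), samples)
  list(matrix = m, groups = groups)
}
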