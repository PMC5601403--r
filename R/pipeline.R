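# Config-driven orchestration of the full analysis: simulate -> qc ->
# quantify -> diff -> group_stats -> enrich. Every stage's outputs are
# recorded in a JSON manifest with file hashes, the seed and the package
# version; a run log records every filter's before/after counts.

default_thresholds <- function() {
  list(alpha = 0.05, min_diff = 0.2, sample_tin = 40, transcript_tin = 60,
       min_coverage = 30, tpm = 1, gsea_min_size = 10, gsea_n_perms = 1000)
}

#' Build a pipeline configuration
#'
#' @param out_dir output directory (created if absent).
#' @param steps stages to run, in dependency order, from `simulate`, `qc`,
#'   `quantify`, `diff`, `group_stats`, `enrich`.
#' @param paths named list of input paths (`models`, `coverage_dir`,
#'   `groups`, optionally `gene_sets` as GMT); filled in automatically when
#'   the `simulate` stage runs.
#' @param thresholds named list overriding the defaults `alpha = 0.05`,
#'   `min_diff = 0.2`, `sample_tin = 40`, `transcript_tin = 60`,
#'   `min_coverage = 30`, `tpm = 1`, `gsea_min_size = 10`.
#' @param simulate named list of [simulation_config()] overrides.
#' @param seed root seed for every stochastic step.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(out_dir, steps = c("simulate", "qc", "quantify",
                                               "diff", "group_stats", "enrich"),
                            paths = list(), thresholds = list(),
                            simulate = list(), seed = 1L) {
  th <- utils::modifyList(default_thresholds(), thresholds)
  if (th$alpha <= 0 || th$alpha >= 1) stop("alpha must lie in (0, 1)")
  if (th$min_diff < 0 || th$min_diff > 1) stop("min_diff must lie in [0, 1]")
  structure(list(out_dir = out_dir, steps = steps, paths = paths,
                 thresholds = th, simulate = simulate, seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file with keys `out_dir`, `steps`, `paths`,
#'   `thresholds`, `simulate`, `seed`.
#' @return a [pipeline_config()].
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  pipeline_config(
    out_dir = y$out_dir %||% stop("config must set out_dir"),
    steps = y$steps %||% c("simulate", "qc", "quantify", "diff",
                           "group_stats", "enrich"),
    paths = y$paths %||% list(),
    thresholds = y$thresholds %||% list(),
    simulate = y$simulate %||% list(),
    seed = y$seed %||% 1L
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run the analysis pipeline
#'
#' Executes the requested stages in dependency order on the configured
#' inputs, writing one TSV per stage under `out_dir`, a run log, and a JSON
#' manifest with the md5 hash of every output, the seed and the package
#' version. A stage whose upstream outputs are missing raises an error
#' naming the stage.
#'
#' @param config a [pipeline_config()] or the path to a YAML config.
#' @return the manifest, invisibly (list with `outputs`, `counts`, `seed`,
#'   `version`).
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_pipeline_config(config)
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(config$out_dir, "run.log")
  log_lines <- character()
  logit <- function(...) {
    line <- paste0(...)
    log_lines <<- c(log_lines, line)
    message(line)
  }
  th <- config$thresholds
  outputs <- list()
  counts <- list()
  st <- new.env(parent = emptyenv()) # shared stage state

  need <- function(stage, what, ok) {
    if (!ok) stop("stage '", stage, "' requires ", what,
                  " from an upstream stage or config paths")
  }

  load_inputs <- function() {
    if (!is.null(st$models)) return(invisible())
    p <- config$paths
    need("qc/quantify", "models, coverage_dir and groups paths",
         !is.null(p$models) && !is.null(p$coverage_dir) && !is.null(p$groups))
    st$models <- read_gene_models(p$models, format = "bed12")
    gr <- read.delim(p$groups, header = FALSE, stringsAsFactors = FALSE)
    st$groups <- stats::setNames(gr[[2]], gr[[1]])
    files <- sort(list.files(p$coverage_dir, pattern = "\\.(bedgraph|bg)(\\.gz)?$",
                             full.names = TRUE))
    st$tracks <- lapply(files, read_bedgraph_all, models = st$models)
    names(st$tracks) <- sub("\\.(bedgraph|bedGraph|bg)(\\.gz)?$", "", basename(files))
    invisible()
  }

  for (stage in config$steps) {
    logit("[", stage, "] starting")
    if (stage == "simulate") {
      sim_args <- utils::modifyList(config$simulate, list(seed = config$seed))
      sim <- do.call(simulation_config, sim_args)
      sim_dir <- file.path(config$out_dir, "sim")
      res <- simulate_cohort(sim, out_dir = sim_dir)
      st$models <- res$models; st$groups <- res$groups; st$tracks <- res$tracks
      st$truth <- res$truth
      config$paths$models <- res$paths[["models"]]
      config$paths$coverage_dir <- file.path(sim_dir, "coverage")
      config$paths$groups <- res$paths[["groups"]]
      outputs[["simulate"]] <- unname(res$paths)
      counts$simulated_genes <- nrow(res$models)
      logit("[simulate] ", nrow(res$models), " genes, ",
            length(res$groups), " samples")
    } else if (stage == "qc") {
      load_inputs()
      tin <- tin_table(st$tracks)
      flt <- apply_tin_filters(tin, sample_cut = th$sample_tin,
                               transcript_cut = th$transcript_tin)
      st$kept_samples <- flt$samples
      st$kept_genes <- flt$genes
      tin_df <- data.frame(gene_id = rownames(tin), tin, check.names = FALSE)
      p <- file.path(config$out_dir, "tin.tsv")
      write_results_table(tin_df, p)
      outputs[["qc"]] <- p
      counts$qc <- list(samples_in = ncol(tin), samples_kept = length(flt$samples),
                        genes_in = nrow(tin), genes_kept = length(flt$genes))
      logit("[qc] samples ", ncol(tin), " -> ", length(flt$samples),
            "; genes ", nrow(tin), " -> ", length(flt$genes))
    } else if (stage == "quantify") {
      load_inputs()
      if (is.null(st$kept_samples)) { # qc not run: keep everything
        st$kept_samples <- names(st$tracks)
        st$kept_genes <- st$models$gene_id
      }
      genes <- intersect(st$models$gene_id, st$kept_genes)
      st$fits <- lapply(genes, function(g) {
        tr <- lapply(st$kept_samples, function(s) st$tracks[[s]][[g]])
        names(tr) <- st$kept_samples
        fit_two_site_model(tr, groups = st$groups[st$kept_samples],
                           min_mean_coverage = th$min_coverage, gene_id = g)
      })
      ok <- vapply(st$fits, function(f) f$status == "ok", logical(1))
      st$pdui <- pdui_matrix(st$fits[ok])
      bp <- data.frame(
        gene_id = genes,
        status = vapply(st$fits, `[[`, character(1), "status"),
        breakpoint = vapply(st$fits, `[[`, integer(1), "breakpoint"),
        utr_length = vapply(st$fits, `[[`, integer(1), "utr_length")
      )
      p1 <- file.path(config$out_dir, "pdui_matrix.tsv")
      write_results_table(data.frame(gene_id = rownames(st$pdui), st$pdui,
                                     check.names = FALSE), p1)
      p2 <- file.path(config$out_dir, "breakpoints.tsv")
      write_results_table(bp, p2)
      outputs[["quantify"]] <- c(p1, p2)
      counts$quantify <- list(genes_in = length(genes), genes_fit = sum(ok))
      logit("[quantify] genes ", length(genes), " -> ", sum(ok),
            " with sufficient coverage")
    } else if (stage == "diff") {
      need("diff", "fitted models (run quantify first)", !is.null(st$fits))
      st$diff <- differential_apa(st$fits, st$groups[st$kept_samples],
                                  alpha = th$alpha, min_diff = th$min_diff)
      p <- file.path(config$out_dir, "differential_apa.tsv")
      write_results_table(st$diff, p)
      outputs[["diff"]] <- p
      counts$diff <- list(tested = nrow(st$diff),
                          significant = sum(st$diff$significant))
      logit("[diff] ", nrow(st$diff), " genes tested, ",
            sum(st$diff$significant), " significant (adj p < ", th$alpha,
            ", |dPDUI| > ", th$min_diff, ")")
    } else if (stage == "group_stats") {
      need("group_stats", "a PDUI matrix (run quantify first)", !is.null(st$pdui))
      need("group_stats", "a differential table (run diff first)", !is.null(st$diff))
      sig <- st$diff$gene_id[st$diff$significant]
      rows <- list()
      if (length(sig) >= 3L) {
        ks <- ks_group_shift(st$pdui[sig, , drop = FALSE],
                             st$groups[st$kept_samples], direction = "greater")
        rows[["ks_shift"]] <- data.frame(
          statistic_name = "ks_shift_D", statistic = ks$statistic,
          p_value = ks$p.value, n = length(sig))
        logit("[group_stats] KS distal shift on ", length(sig),
              " significant genes: D = ", signif(ks$statistic, 4),
              ", p = ", signif(ks$p.value, 4))
      } else {
        logit("[group_stats] fewer than 3 significant genes: KS shift skipped")
      }
      if (nrow(st$pdui) >= 8L) {
        vq <- variability_quartiles(st$pdui, st$groups[st$kept_samples],
                                    control = "A")
        rows[["vq"]] <- data.frame(
          statistic_name = "variability_quartiles_W", statistic = vq$statistic,
          p_value = vq$p.value, n = nrow(vq$table))
        logit("[group_stats] variability quartiles: W = ", vq$statistic,
              ", p = ", signif(vq$p.value, 4))
      }
      p <- file.path(config$out_dir, "group_stats.tsv")
      write_results_table(do.call(rbind, rows), p)
      outputs[["group_stats"]] <- p
    } else if (stage == "enrich") {
      need("enrich", "a PDUI matrix (run quantify first)", !is.null(st$pdui))
      need("enrich", "a differential table (run diff first)", !is.null(st$diff))
      universe <- st$diff$gene_id
      sig <- st$diff$gene_id[st$diff$significant]
      if (!is.null(config$paths$gene_sets)) {
        sets <- read_gene_sets(config$paths$gene_sets, format = "gmt")
      } else {
        # no gene sets supplied: build seeded demonstration sets from the
        # tested universe so the stage is exercised end to end
        set.seed(config$seed)
        sets <- list(
          demo_set_1 = sample(universe, max(10L, length(universe) %/% 4L)),
          demo_set_2 = sample(universe, max(10L, length(universe) %/% 4L))
        )
        logit("[enrich] no gene_sets path: using seeded demonstration sets")
      }
      lens <- stats::setNames(st$models$length_weight, st$models$gene_id)
      res_overlap <- if (length(sig) >= 1L) {
        set.seed(config$seed + 1L)
        length_aware_enrichment(sig, sets, universe, lens,
                                method = "resampling", n_resamples = 2000L)
      } else NULL
      set.seed(config$seed + 2L)
      res_gsea <- gsea_pdui(st$pdui, st$groups[st$kept_samples], sets,
                            min_size = th$gsea_min_size,
                            n_perms = th$gsea_n_perms)
      out_files <- character()
      if (!is.null(res_overlap)) {
        p <- file.path(config$out_dir, "enrichment_overlap.tsv")
        write_results_table(res_overlap, p)
        out_files <- c(out_files, p)
      }
      p <- file.path(config$out_dir, "enrichment_gsea.tsv")
      write_results_table(res_gsea, p)
      out_files <- c(out_files, p)
      outputs[["enrich"]] <- out_files
      counts$enrich <- list(sets = length(sets), gsea_tested = nrow(res_gsea))
      logit("[enrich] ", length(sets), " sets; ", nrow(res_gsea),
            " tested by GSEA")
    } else {
      stop("unknown pipeline stage: ", stage)
    }
  }

  files <- unlist(outputs, use.names = FALSE)
  manifest <- list(
    package = "apashift",
    version = as.character(utils::packageVersion("apashift")),
    seed = config$seed,
    thresholds = th,
    outputs = lapply(files, function(f) list(path = f, md5 = unname(tools::md5sum(f)))),
    counts = counts
  )
  writeLines(log_lines, log_path)
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}
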