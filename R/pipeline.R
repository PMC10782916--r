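# End-to-end orchestration: configuration validation, staged execution with
# resume, structured logging, and run reports. No new computation lives here.

#' Build and validate a pipeline configuration
#'
#' @param genome Path to the reference FASTA.
#' @param r1,r2 Paired FASTQ paths.
#' @param genes Path to gene models (BED6/GFF3); optional, needed for driver
#'   annotation and co-occurrence.
#' @param drivers Path to a driver gene list TSV; optional.
#' @param outdir Output/run directory.
#' @param sample_id Sample identifier.
#' @param tag Transposon tag sequence.
#' @param min_reads_per_site,min_sites QC thresholds.
#' @param min_support,cut,min_cluster_sites Clustering parameters.
#' @param promoter_window Annotation promoter window (bases).
#' @param n_iter Permutation trials (0 disables the co-occurrence stage).
#' @param seed Master seed.
#' @param stages Character vector of stages to run, in order, among
#'   \code{"process-reads"}, \code{"call-insertions"}, \code{"cluster"},
#'   \code{"cooccur"}.
#' @return A validated list of class \code{"sb_pipeline_config"}.
#' @export
pipeline_config <- function(genome, r1, r2, outdir, sample_id = "sample",
                            genes = NULL, drivers = NULL,
                            tag = "TGTATGTAAACTTCCGACTT",
                            min_reads_per_site = 10L, min_sites = 2L,
                            min_support = 2L, cut = 0.5,
                            min_cluster_sites = 2L,
                            promoter_window = 40000L,
                            n_iter = 10000L, seed = 1L,
                            stages = c("process-reads", "call-insertions",
                                       "cluster", "cooccur")) {
  cfg <- list(genome = genome, r1 = r1, r2 = r2, genes = genes,
              drivers = drivers, outdir = outdir, sample_id = sample_id,
              tag = toupper(tag),
              min_reads_per_site = as.integer(min_reads_per_site),
              min_sites = as.integer(min_sites),
              min_support = as.integer(min_support), cut = cut,
              min_cluster_sites = as.integer(min_cluster_sites),
              promoter_window = as.integer(promoter_window),
              n_iter = as.integer(n_iter), seed = as.integer(seed),
              stages = stages)
  for (p in c("genome", "r1", "r2"))
    if (!file.exists(cfg[[p]])) stopf("config: %s path not found: %s", p, cfg[[p]])
  for (p in c("genes", "drivers"))
    if (!is.null(cfg[[p]]) && !file.exists(cfg[[p]]))
      stopf("config: %s path not found: %s", p, cfg[[p]])
  bad <- setdiff(stages, c("process-reads", "call-insertions", "cluster",
                           "cooccur"))
  if (length(bad)) stopf("config: unknown stage(s): %s", paste(bad, collapse = ", "))
  if (("cooccur" %in% stages || !is.null(cfg$drivers)) && is.null(cfg$genes))
    stopf("config: 'genes' is required for driver annotation / co-occurrence")
  class(cfg) <- "sb_pipeline_config"
  cfg
}

#' @keywords internal
config_hash <- function(config) {
  fnv1a32(jsonlite::toJSON(unclass(config), auto_unbox = TRUE))
}

#' @keywords internal
stage_log <- function(run_dir, stage, status, t0) {
  rec <- list(stage = stage, status = status,
              elapsed_s = round(as.numeric(Sys.time()) - t0, 3),
              time = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"))
  cat(jsonlite::toJSON(rec, auto_unbox = TRUE), "\n",
      file = file.path(run_dir, "pipeline.log"), append = TRUE, sep = "")
}

#' Run the pipeline end to end
#'
#' Executes the configured stages in order (process-reads, call-insertions,
#' cluster, cooccur), each writing its outputs under \code{outdir} with the
#' config hash in a header line, plus a structured JSON-lines log. A
#' completed stage leaves a \code{.done.<stage>} marker; rerunning with
#' \code{resume = TRUE} skips completed stages (same config hash only).
#'
#' @param config An \code{"sb_pipeline_config"}.
#' @param resume Skip stages whose done-marker (with matching config hash)
#'   exists (default \code{TRUE}).
#' @return The run directory path, invisibly. Intermediate objects are also
#'   saved in the returned environment attribute \code{"state"} for
#'   programmatic access.
#' @export
run_pipeline <- function(config, resume = TRUE) {
  stopifnot(inherits(config, "sb_pipeline_config"))
  dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
  hash <- config_hash(config)
  hdr <- c(paste("config_hash:", hash), paste("sample:", config$sample_id))
  jsonlite::write_json(c(unclass(config), list(config_hash = hash)),
                       file.path(config$outdir, "config.json"),
                       auto_unbox = TRUE, null = "null")
  marker <- function(stage) file.path(config$outdir,
                                      paste0(".done.", stage, ".", hash))
  state <- new.env(parent = emptyenv())

  genome <- read_genome(config$genome)
  annotation <- NULL
  if (!is.null(config$genes))
    annotation <- build_annotation(read_genes(config$genes),
                                   promoter_window = config$promoter_window)

  run_stage <- function(stage, fun) {
    t0 <- as.numeric(Sys.time())
    if (resume && file.exists(marker(stage))) {
      stage_log(config$outdir, stage, "skipped_done", t0)
      return(invisible(NULL))
    }
    ok <- tryCatch({ fun(); TRUE },
                   error = function(e) {
                     stage_log(config$outdir, stage, paste("error:",
                                                           conditionMessage(e)), t0)
                     stopf("stage '%s' failed: %s", stage, conditionMessage(e))
                   })
    file.create(marker(stage))
    stage_log(config$outdir, stage, "ok", t0)
  }

  jx_path <- file.path(config$outdir, "junctions.tsv")
  if ("process-reads" %in% config$stages)
    run_stage("process-reads", function() {
      jx <- process_reads(config$r1, config$r2, genome, config$tag)
      state$junctions <- jx
      write_tsv(jx$junctions, jx_path, hdr)
      jsonlite::write_json(as.list(jx$audit),
                           file.path(config$outdir, "read_audit.json"),
                           auto_unbox = TRUE)
    })

  if ("call-insertions" %in% config$stages)
    run_stage("call-insertions", function() {
      jx <- if (!is.null(state$junctions)) state$junctions$junctions
            else read_tsv(jx_path)
      cells <- aggregate_cells(jx)
      qc <- qc_filter(cells, config$min_reads_per_site, config$min_sites)
      smp <- build_sample(qc, config$sample_id)
      state$sample <- smp
      write_tsv(smp$cells, file.path(config$outdir, "cell_sites.tsv"), hdr)
      write_tsv(smp$sites, file.path(config$outdir, "sites.tsv"), hdr)
      jsonlite::write_json(smp$audit, file.path(config$outdir, "qc.json"),
                           auto_unbox = TRUE)
    })

  load_sample <- function() {
    if (is.null(state$sample)) {
      cells <- read_tsv(file.path(config$outdir, "cell_sites.tsv"))
      state$sample <- build_sample(
        cells[, c("barcode", "contig", "pos", "orientation", "reads")],
        config$sample_id)
    }
    state$sample
  }

  if ("cluster" %in% config$stages)
    run_stage("cluster", function() {
      smp <- load_sample()
      fit <- fit_subclones(smp, min_support = config$min_support,
                           cut = config$cut,
                           min_cluster_sites = config$min_cluster_sites)
      if (!is.null(annotation) && !is.null(config$drivers))
        fit <- annotate_drivers(fit, config$drivers, annotation)
      asg <- assign_cells(smp, fit)
      state$fit <- fit
      state$assignment <- asg
      write_tsv(subclone_table(fit, asg),
                file.path(config$outdir, "subclones.tsv"), hdr)
      write_tsv(data.frame(barcode = names(asg), assignment = unname(asg)),
                file.path(config$outdir, "cell_assignment.tsv"), hdr)
      adj <- Matrix::summary(build_adjacency(smp))
      write_tsv(data.frame(site_i = rownames(state$fit$adjacency)[adj$i],
                           site_j = colnames(state$fit$adjacency)[adj$j],
                           n_cells = adj$x),
                file.path(config$outdir, "adjacency.tsv"), hdr)
    })

  if ("cooccur" %in% config$stages && config$n_iter > 0L)
    run_stage("cooccur", function() {
      smp <- load_sample()
      ta <- build_ta_index(genome)
      cx <- cooccurrence_test(smp, annotation, ta,
                              n_iter = config$n_iter,
                              seed = derive_seed(config$seed, 4L))
      state$cooccur <- cx
      write_tsv(cx$results, file.path(config$outdir, "cooccurrence.tsv"), hdr)
      jsonlite::write_json(list(seed = cx$seed, n_iter = cx$n_iter,
                                c = stats::setNames(as.list(cx$results$c),
                                                    paste(cx$results$gene_a,
                                                          cx$results$gene_b,
                                                          sep = "|"))),
                           file.path(config$outdir, "permutation_audit.json"),
                           auto_unbox = TRUE)
    })

  out <- config$outdir
  attr(out, "state") <- state
  invisible(out)
}

#' Summarize a pipeline run directory
#'
#' @param run_dir A directory produced by \code{\link{run_pipeline}}.
#' @return A list (also written as \code{report.json}/\code{report.tsv} in
#'   the run directory): per-sample cell counts pre/post QC, subclone count
#'   and sizes, percent unassigned/doublet-suspect cells, driver genes per
#'   subclone, and significant co-occurring pairs; stages that did not run
#'   are flagged \code{"skipped"}.
#' @export
pipeline_report <- function(run_dir) {
  rep <- list(run_dir = run_dir)
  qc_path <- file.path(run_dir, "qc.json")
  rep$qc <- if (file.exists(qc_path)) jsonlite::read_json(qc_path) else "skipped"
  sub_path <- file.path(run_dir, "subclones.tsv")
  if (file.exists(sub_path)) {
    st <- read_tsv(sub_path)
    asg <- read_tsv(file.path(run_dir, "cell_assignment.tsv"))
    tab <- table(asg$assignment)
    n <- nrow(asg)
    rep$subclones <- list(
      n_subclones = nrow(st),
      sites_per_subclone = st$n_sites,
      cells_per_subclone = if ("n_cells" %in% names(st)) st$n_cells else NULL,
      pct_unassigned = round(100 * sum(asg$assignment == "UNASSIGNED") / n, 2),
      pct_multi = round(100 * sum(asg$assignment == "MULTI") / n, 2),
      driver_genes = if ("driver_genes" %in% names(st))
        stats::setNames(as.list(st$driver_genes), st$subclone) else NULL)
  } else rep$subclones <- "skipped"
  cx_path <- file.path(run_dir, "cooccurrence.tsv")
  if (file.exists(cx_path)) {
    cx <- read_tsv(cx_path)
    rep$cooccurrence <- list(n_pairs = nrow(cx),
                             n_significant = sum(cx$p_adj <= 0.05),
                             top = utils::head(cx[order(cx$p_est), ], 10))
  } else rep$cooccurrence <- "skipped"
  jsonlite::write_json(rep, file.path(run_dir, "report.json"),
                       auto_unbox = TRUE, dataframe = "rows", null = "null")
  if (is.list(rep$subclones))
    write_tsv(read_tsv(sub_path), file.path(run_dir, "report.tsv"))
  rep
}
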