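#' Pipeline configuration
#'
#' Collects every tunable of the end-to-end analysis with its default:
#' 1 kb windows at a 5% window FDR, genome-wide per-probe threshold
#' 1.09e-7, five cell-type components over 500 selected probes, 1000
#' bootstrap replicates at FWER 0.1 for the bump-hunting cross-check, and
#' gene-set testing at a minimum overlap of 2 and FDR 0.05.
#'
#' @param window_width sliding-window width in bp.
#' @param window_fdr q-value threshold for significant windows.
#' @param probe_threshold genome-wide per-probe significance threshold.
#' @param refactor_k,refactor_t cell-type components and selected sites.
#' @param celltype_correction run the sparse-PCA correction stage.
#' @param normalisation run the covariate-normalisation stage.
#' @param bumphunter_b bootstrap replicates (0 disables the cross-check).
#' @param fwer_threshold bootstrap FWER significance threshold.
#' @param min_overlap,pathway_fdr gene-set testing parameters.
#' @param max_missing,max_detection_fail,detection_alpha probe QC thresholds;
#'   `max_missing = NULL` derives the missingness threshold from the
#'   binomial rule via [missingness_threshold()] with `base_rate`.
#' @param base_rate assumed per-entry missingness rate for the binomial rule.
#' @param seed integer seed for all stochastic stages.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(window_width = 1000, window_fdr = 0.05,
                            probe_threshold = 1.09e-7,
                            refactor_k = 5, refactor_t = 500,
                            celltype_correction = TRUE, normalisation = TRUE,
                            bumphunter_b = 1000, fwer_threshold = 0.1,
                            min_overlap = 2, pathway_fdr = 0.05,
                            max_missing = 11, max_detection_fail = 5,
                            detection_alpha = 0.001, base_rate = 0.01,
                            seed = 1L) {
  cfg <- list(window_width = window_width, window_fdr = window_fdr,
              probe_threshold = probe_threshold, refactor_k = refactor_k,
              refactor_t = refactor_t,
              celltype_correction = celltype_correction,
              normalisation = normalisation,
              bumphunter_b = bumphunter_b, fwer_threshold = fwer_threshold,
              min_overlap = min_overlap, pathway_fdr = pathway_fdr,
              max_missing = max_missing,
              max_detection_fail = max_detection_fail,
              detection_alpha = detection_alpha, base_rate = base_rate,
              seed = as.integer(seed))
  stopifnot(cfg$window_width >= 1, cfg$window_fdr > 0, cfg$window_fdr < 1,
            cfg$fwer_threshold > 0, cfg$fwer_threshold < 1)
  class(cfg) <- "pipeline_config"
  cfg
}

#' Load a pipeline configuration from a YAML file
#'
#' Fields absent from the file keep their [pipeline_config()] defaults.
#'
#' @param path YAML file path.
#' @return a `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  vals <- yaml::read_yaml(path)
  known <- names(formals(pipeline_config))
  unknown <- setdiff(names(vals), known)
  if (length(unknown))
    stop("unknown config fields: ", paste(unknown, collapse = ", "))
  do.call(pipeline_config, vals)
}

.config_checksum <- function(cfg) {
  s <- paste(names(cfg), vapply(cfg, function(x) paste(format(x), collapse = ","),
                                character(1)),
             sep = "=", collapse = ";")
  v <- utf8ToInt(s)
  h <- 0
  for (x in v) h <- (h * 31 + x) %% 2147483647
  sprintf("%08x", as.integer(h))
}

#' Run the full differential-methylation pipeline
#'
#' Stage order: probe QC filter, covariate normalisation, cell-type
#' correction, M-value association scan with inflation diagnostics, sliding
#' window DMR calling with q-value FDR, optional bump-hunting cross-check
#' with bootstrap FWER, the overlap between the two region sets, and
#' feature/gene-set enrichment. Identical inputs, configuration and seed
#' give identical outputs.
#'
#' @param ds a [meth_set()] (e.g. from [simulate_dataset()] or
#'   [read_meth_set()]).
#' @param config a [pipeline_config()].
#' @param gmt_sets optional named list of gene sets for pathway enrichment.
#' @param out_dir optional directory; when given, all result tables, a BED
#'   file of DMRs, a JSON diagnostics report and a run log (recording the
#'   configuration in effect, its checksum and the seed) are written there.
#' @return list of class `ewas_pipeline` with elements `qc`, `dataset`
#'   (corrected), `components`, `scan`, `inflation`, `windows`, `dmrs`,
#'   `bumps`, `method_overlap`, `feature_enrichment`, `pathway_enrichment`,
#'   `config`.
#' @export
run_pipeline <- function(ds, config = pipeline_config(), gmt_sets = NULL,
                         out_dir = NULL) {
  stopifnot(inherits(ds, "meth_set"))
  set.seed(config$seed)
  log_lines <- c(
    sprintf("methwindow run, config checksum %s, seed %d",
            .config_checksum(config), config$seed),
    sprintf("  %s = %s", names(config),
            vapply(config, function(x) paste(format(x), collapse = ","), character(1)))
  )

  max_missing <- config$max_missing
  if (is.null(max_missing)) {
    max_missing <- missingness_threshold(ncol(ds$beta), nrow(ds$beta),
                                         config$base_rate)
    log_lines <- c(log_lines,
                   sprintf("derived max_missing = %d from the binomial rule", max_missing))
  }
  flt <- filter_probes(ds, max_missing, config$max_detection_fail,
                       config$detection_alpha)
  work <- flt$dataset

  if (isTRUE(config$normalisation)) work <- normalize_probes(work)

  comps <- NULL
  if (isTRUE(config$celltype_correction) && config$refactor_k > 0) {
    comps <- refactor_components(work$beta, K = config$refactor_k,
                                 t = min(config$refactor_t, nrow(work$beta)))
    work <- meth_set(regress_out_components(work$beta, comps),
                     work$manifest, work$samples, work$detection_p)
  }

  scan <- genome_scan(work)
  ok <- !is.na(scan$p)
  infl <- if (any(ok)) inflation_lambda(scan$p[ok]) else NULL
  band <- if (any(ok)) qq_band(sum(ok)) else NULL
  windows <- make_windows(scan[ok, c("probe_id", "chrom", "pos")],
                          width = config$window_width)
  windows <- score_windows(windows, scan$p[ok])
  windows$q <- storey_qvalues(windows$p)
  dmrs <- merge_significant_windows(windows, scan, config$window_fdr,
                                    manifest = work$manifest)

  bumps <- NULL
  overlap <- NULL
  if (config$bumphunter_b > 0) {
    bumps <- bumphunt(work, B = config$bumphunter_b,
                      seed = config$seed + 1L)
    overlap <- region_overlap(dmrs, bumps)
  }

  fe <- NULL
  pe <- NULL
  if (nrow(dmrs)) {
    ids <- unique(unlist(dmrs$probe_ids))
    fe <- lapply(intersect(c("island_relation", "gene_feature", "dnase_hs"),
                           names(work$manifest)),
                 function(f) feature_enrichment(ids, work$manifest, f))
    names(fe) <- intersect(c("island_relation", "gene_feature", "dnase_hs"),
                           names(work$manifest))
    if (!is.null(gmt_sets)) {
      genes <- unique(stats::na.omit(unlist(strsplit(dmrs$nearest_genes, ","))))
      bgg <- unique(stats::na.omit(work$manifest$nearest_gene))
      if (length(genes))
        pe <- geneset_enrichment(genes, gmt_sets, bgg,
                                 min_overlap = config$min_overlap,
                                 fdr = config$pathway_fdr)
    }
  }

  res <- structure(list(
    qc = flt$qc, dataset = work, components = comps, scan = scan,
    inflation = infl, qq = band, windows = windows, dmrs = dmrs,
    bumps = bumps, method_overlap = overlap, feature_enrichment = fe,
    pathway_enrichment = pe, config = config
  ), class = "ewas_pipeline")

  if (!is.null(out_dir)) .write_pipeline_outputs(res, out_dir, log_lines)
  res
}

.write_pipeline_outputs <- function(res, out_dir, log_lines) {
  ok <- FALSE
  on.exit(if (!ok) unlink(out_dir, recursive = TRUE), add = TRUE)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  write_assoc_tsv(res$scan, file.path(out_dir, "association.tsv"))
  write_dmr_tsv(res$dmrs, file.path(out_dir, "dmrs.tsv"))
  write_regions_bed(res$dmrs, file.path(out_dir, "dmrs.bed"), score_col = "fdr_q")
  if (!is.null(res$bumps)) {
    b <- as.data.frame(res$bumps)
    b$probe_ids <- vapply(b$probe_ids, paste, character(1), collapse = ",")
    .write_tsv(b, file.path(out_dir, "bumps.tsv"))
  }
  if (!is.null(res$feature_enrichment)) {
    for (nm in names(res$feature_enrichment))
      .write_tsv(res$feature_enrichment[[nm]],
                 file.path(out_dir, paste0("enrichment_", nm, ".tsv")))
  }
  if (!is.null(res$pathway_enrichment))
    .write_tsv(res$pathway_enrichment, file.path(out_dir, "enrichment_pathways.tsv"))
  diag <- list(lambda = res$inflation$lambda,
               expected_median = res$inflation$expected_median,
               n_tests = res$inflation$n_tests,
               n_dmrs = nrow(res$dmrs),
               config_checksum = .config_checksum(res$config),
               seed = res$config$seed)
  jsonlite::write_json(diag, file.path(out_dir, "diagnostics.json"),
                       auto_unbox = TRUE, digits = NA)
  writeLines(c(log_lines,
               sprintf("probes after QC: %d", res$qc$n_probes_out),
               sprintf("lambda = %.4f", res$inflation$lambda),
               sprintf("DMRs at FDR %.2f: %d", res$config$window_fdr,
                       nrow(res$dmrs))),
             file.path(out_dir, "run.log"))
  ok <- TRUE
  invisible(out_dir)
}

#' @export
print.ewas_pipeline <- function(x, ...) {
  cat("ewas_pipeline result\n")
  print(x$qc)
  print(x$inflation)
  cat("  windows scored:", nrow(x$windows), "\n")
  cat("  DMRs at FDR", x$config$window_fdr, ":", nrow(x$dmrs), "\n")
  if (!is.null(x$bumps))
    cat("  bump candidates:", nrow(x$bumps), "\n")
  invisible(x)
}
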