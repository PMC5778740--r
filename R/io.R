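#' @name methwindow-io
#' @title Tabular readers and writers
#' @description
#' All tabular interchange uses tab-separated text with a header row.
#' Internal genomic coordinates are 1-based inclusive (the array-manifest
#' convention); BED export converts to 0-based half-open in one place,
#' [write_regions_bed()]. Every writer/reader pair round-trips exactly.
NULL

.write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA")
}

.read_tsv <- function(path) {
  utils::read.delim(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE,
                    check.names = FALSE)
}

#' @rdname methwindow-io
#' @param manifest a probe manifest.
#' @param path file path.
#' @export
write_manifest <- function(manifest, path) {
  cols <- c("probe_id", "chrom", "pos", "island_relation", "gene_feature",
            "nearest_gene", "dnase_hs")
  .write_tsv(manifest[, cols], path)
}

#' @rdname methwindow-io
#' @export
read_manifest <- function(path) {
  man <- .read_tsv(path)
  need <- c("probe_id", "chrom", "pos", "island_relation", "gene_feature",
            "nearest_gene", "dnase_hs")
  miss <- setdiff(need, names(man))
  if (length(miss)) stop("manifest file lacks columns: ", paste(miss, collapse = ", "))
  man$pos <- as.integer(man$pos)
  man$dnase_hs <- as.logical(man$dnase_hs)
  man
}

#' @rdname methwindow-io
#' @param m numeric matrix with row and column names.
#' @export
write_matrix_tsv <- function(m, path) {
  df <- data.frame(probe_id = rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  .write_tsv(df, path)
}

#' @rdname methwindow-io
#' @export
read_matrix_tsv <- function(path) {
  df <- .read_tsv(path)
  if (names(df)[1] != "probe_id") stop("matrix file must start with a probe_id column")
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df$probe_id
  storage.mode(m) <- "double"
  m
}

#' @rdname methwindow-io
#' @param samples a sample sheet.
#' @export
write_sample_sheet <- function(samples, path) .write_tsv(samples, path)

#' @rdname methwindow-io
#' @export
read_sample_sheet <- function(path) {
  s <- .read_tsv(path)
  if (!"sample_id" %in% names(s)) stop("sample sheet lacks a sample_id column")
  for (v in c("photophobia", "nausea", "disability"))
    if (v %in% names(s)) s[[v]] <- as.logical(s[[v]])
  s
}

#' @rdname methwindow-io
#' @param regions data.frame with `chrom`, `start`, `end` (1-based
#'   inclusive) and optionally `delta_beta` or other score columns.
#' @param score_col optional column written to the BED score slot.
#' @details BED output is 0-based half-open: an internal region
#'   \[100, 199\] is written as `99 199`.
#' @export
write_regions_bed <- function(regions, path, score_col = NULL) {
  if (!nrow(regions)) {
    writeLines(character(0), path)
    return(invisible(path))
  }
  name <- if (!is.null(regions$direction)) regions$direction
    else sprintf("region_%d", seq_len(nrow(regions)))
  bed <- data.frame(chrom = regions$chrom,
                    start = regions$start - 1L,  # to 0-based half-open
                    end = regions$end,
                    name = name)
  if (!is.null(score_col) && score_col %in% names(regions))
    bed$score <- regions[[score_col]]
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname methwindow-io
#' @export
read_regions_bed <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) {
    return(data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), name = character(0)))
  }
  df <- utils::read.table(text = lines, sep = "\t", header = FALSE,
                          stringsAsFactors = FALSE)
  names(df)[1:3] <- c("chrom", "start", "end")
  if (ncol(df) >= 4) names(df)[4] <- "name"
  if (ncol(df) >= 5) names(df)[5] <- "score"
  df$start <- as.integer(df$start) + 1L  # back to 1-based inclusive
  df$end <- as.integer(df$end)
  df
}

#' @rdname methwindow-io
#' @param dmrs a `dmr_set`.
#' @details The DMR TSV mirrors the region-table column set:
#'   chromosome, start, end, direction, P value, FDR, probe count, genes.
#' @export
write_dmr_tsv <- function(dmrs, path) {
  df <- data.frame(
    chromosome = dmrs$chrom, start = dmrs$start, end = dmrs$end,
    direction = dmrs$direction, p_value = dmrs$p, fdr = dmrs$fdr_q,
    n_probes = dmrs$n_probes, genes = dmrs$nearest_genes,
    stringsAsFactors = FALSE
  )
  .write_tsv(df, path)
}

#' @rdname methwindow-io
#' @param scan an `assoc_scan`.
#' @export
write_assoc_tsv <- function(scan, path) {
  .write_tsv(as.data.frame(scan)[, c("probe_id", "chrom", "pos", "coef", "se",
                                     "lrt_stat", "df", "p", "mean_beta_case",
                                     "mean_beta_control", "delta_beta")], path)
}

#' Write a full dataset to a directory of TSV files
#'
#' @param ds a [meth_set()].
#' @param dir output directory (created if needed).
#' @return invisibly, the directory.
#' @export
write_meth_set <- function(ds, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_manifest(ds$manifest, file.path(dir, "manifest.tsv"))
  write_matrix_tsv(ds$beta, file.path(dir, "beta.tsv"))
  if (!is.null(ds$detection_p))
    write_matrix_tsv(ds$detection_p, file.path(dir, "detection_p.tsv"))
  write_sample_sheet(ds$samples, file.path(dir, "samples.tsv"))
  invisible(dir)
}

#' Read a dataset written by [write_meth_set()]
#'
#' @param dir directory containing `manifest.tsv`, `beta.tsv`,
#'   `samples.tsv` and optionally `detection_p.tsv`.
#' @return a [meth_set()].
#' @export
read_meth_set <- function(dir) {
  man <- read_manifest(file.path(dir, "manifest.tsv"))
  beta <- read_matrix_tsv(file.path(dir, "beta.tsv"))
  samples <- read_sample_sheet(file.path(dir, "samples.tsv"))
  dp <- NULL
  if (file.exists(file.path(dir, "detection_p.tsv")))
    dp <- read_matrix_tsv(file.path(dir, "detection_p.tsv"))
  meth_set(beta, man, samples, dp)
}
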