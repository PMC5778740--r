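#' Genomic-feature enrichment of DMR probes
#'
#' For each level of a manifest annotation (CpG-island relation, gene
#' feature, or the DNase hypersensitivity flag), tests whether DMR-associated
#' probes overlap the feature more often than the array background with a
#' two-sided Fisher's exact test. The background is the full manifest,
#' including the DMR probes themselves (the set is compared against the whole
#' array); set `exclusive_background = TRUE` to remove them.
#'
#' @param dmr_probe_ids character vector of probe ids in significant regions.
#' @param manifest probe manifest containing the ids.
#' @param feature_field manifest column to test
#'   (`"island_relation"`, `"gene_feature"` or `"dnase_hs"`).
#' @param exclusive_background drop DMR probes from the background counts.
#' @return data.frame of class `enrichment_table`: one row per feature level
#'   with the 2x2 counts `a` (set, in feature), `b` (set, not), `c`
#'   (background, in feature), `d` (background, not), `odds_ratio`
#'   (a*d / b*c, `Inf` sentinel for degenerate tables), `p`, `fdr_q`.
#' @export
feature_enrichment <- function(dmr_probe_ids, manifest,
                               feature_field = "island_relation",
                               exclusive_background = FALSE) {
  if (!length(dmr_probe_ids)) stop("empty DMR probe set")
  if (!feature_field %in% names(manifest))
    stop("manifest lacks column ", feature_field)
  if (!all(dmr_probe_ids %in% manifest$probe_id))
    stop("DMR probes must be a subset of the manifest")
  feat <- manifest[[feature_field]]
  if (is.logical(feat)) feat <- ifelse(feat, "TRUE", "FALSE")
  in_set <- manifest$probe_id %in% dmr_probe_ids
  bg <- if (exclusive_background) !in_set else rep(TRUE, nrow(manifest))
  levels_ <- sort(unique(feat))
  rows <- lapply(levels_, function(lv) {
    a <- sum(in_set & feat == lv)
    b <- sum(in_set & feat != lv)
    cc <- sum(bg & feat == lv)
    d <- sum(bg & feat != lv)
    p <- stats::fisher.test(matrix(c(a, b, cc, d), 2))$p.value
    or <- if (b * cc == 0) {
      if (a * d == 0) NaN else Inf
    } else (a * d) / (b * cc)
    data.frame(feature = lv, a = a, b = b, c = cc, d = d,
               odds_ratio = or, p = p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$fdr_q <- stats::p.adjust(out$p, method = "BH")
  class(out) <- c("enrichment_table", "data.frame")
  out
}

#' Map regions to their nearest genes
#'
#' Genes overlapping a region are returned; otherwise the minimum-distance
#' gene(s) on the same chromosome, all ties included. Regions on
#' chromosomes absent from the annotation are annotated `NA` with a warning.
#'
#' @param regions data.frame with `chrom`, `start`, `end` (1-based
#'   inclusive).
#' @param gene_annotation data.frame with `gene`, `chrom`, `start`, `end`.
#' @return list (one element per region) of character vectors of gene names.
#' @export
nearest_gene <- function(regions, gene_annotation) {
  n <- nrow(regions)
  if (!n) return(list())
  if (!nrow(gene_annotation)) return(rep(list(NA_character_), n))
  gr <- GenomicRanges::GRanges(regions$chrom,
                               IRanges::IRanges(regions$start, regions$end))
  gg <- GenomicRanges::GRanges(gene_annotation$chrom,
                               IRanges::IRanges(gene_annotation$start,
                                                gene_annotation$end))
  out <- rep(list(character(0)), n)
  ov <- suppressWarnings(GenomicRanges::findOverlaps(gr, gg))
  for (h in seq_along(ov)) {
    q <- S4Vectors::queryHits(ov)[h]
    out[[q]] <- c(out[[q]], gene_annotation$gene[S4Vectors::subjectHits(ov)[h]])
  }
  todo <- which(!lengths(out))
  missing_chrom <- FALSE
  for (q in todo) {
    same <- which(gene_annotation$chrom == regions$chrom[q])
    if (!length(same)) {
      out[[q]] <- NA_character_
      missing_chrom <- TRUE
      next
    }
    d <- pmax(0, pmax(gene_annotation$start[same] - regions$end[q],
                      regions$start[q] - gene_annotation$end[same]))
    out[[q]] <- gene_annotation$gene[same[d == min(d)]]
  }
  if (missing_chrom)
    warning("some regions lie on chromosomes absent from the gene annotation")
  lapply(out, unique)
}

#' Read a GMT gene-set file
#'
#' Standard tab-separated format: set name, description, then member genes.
#' Empty fields from trailing tabs are dropped.
#'
#' @param path GMT file path.
#' @return named list of gene-id character vectors, with a `description`
#'   attribute per element.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  sets <- list()
  for (ln in lines) {
    f <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    if (length(f) < 2) stop("malformed GMT line: ", substr(ln, 1, 50))
    genes <- unique(f[-(1:2)][nzchar(f[-(1:2)])])
    s <- genes
    attr(s, "description") <- f[2]
    sets[[f[1]]] <- s
  }
  sets
}

#' Write a GMT gene-set file
#'
#' @param sets named list of gene vectors (optionally carrying a
#'   `description` attribute).
#' @param path output path.
#' @export
write_gmt <- function(sets, path) {
  lines <- vapply(names(sets), function(nm) {
    desc <- attr(sets[[nm]], "description")
    if (is.null(desc)) desc <- nm
    paste(c(nm, desc, as.character(sets[[nm]])), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
}

#' Gene-set over-representation of DMR genes
#'
#' Hypergeometric upper-tail test of each gene set against the background,
#' testing only sets whose overlap with the gene list reaches
#' `min_overlap`; Benjamini-Hochberg q-values are computed across the tested
#' sets.
#'
#' @param gene_list character vector of DMR-associated genes.
#' @param gmt_sets named list of gene sets (see [read_gmt()]).
#' @param background_genes character vector of background genes (must
#'   contain `gene_list`).
#' @param min_overlap minimum list/set overlap for a set to be tested
#'   (default 2).
#' @param fdr significance threshold recorded in the `significant` column.
#' @return data.frame of class `enrichment_table`: `set`, 2x2 counts,
#'   `odds_ratio`, `p`, `fdr_q`, `significant`, `overlap_genes`.
#' @export
geneset_enrichment <- function(gene_list, gmt_sets, background_genes,
                               min_overlap = 2, fdr = 0.05) {
  gene_list <- unique(gene_list[!is.na(gene_list)])
  background_genes <- unique(background_genes[!is.na(background_genes)])
  if (!all(gene_list %in% background_genes))
    stop("`background_genes` must contain every gene in `gene_list`")
  empty <- data.frame(set = character(0), a = integer(0), b = integer(0),
                      c = integer(0), d = integer(0), odds_ratio = numeric(0),
                      p = numeric(0), fdr_q = numeric(0),
                      significant = logical(0), overlap_genes = character(0),
                      stringsAsFactors = FALSE)
  class(empty) <- c("enrichment_table", "data.frame")
  if (!length(gmt_sets)) return(empty)
  N <- length(background_genes)
  nl <- length(gene_list)
  rows <- lapply(names(gmt_sets), function(nm) {
    set_bg <- intersect(as.character(gmt_sets[[nm]]), background_genes)
    ov <- intersect(gene_list, set_bg)
    k <- length(ov)
    if (k < min_overlap) return(NULL)
    m <- length(set_bg)
    p <- stats::phyper(k - 1, m, N - m, nl, lower.tail = FALSE)
    a <- k; b <- nl - k; cc <- m; d <- N - m
    or <- if (b * cc == 0) {
      if (a * d == 0) NaN else Inf
    } else (a * d) / (b * cc)
    data.frame(set = nm, a = a, b = b, c = cc, d = d, odds_ratio = or, p = p,
               overlap_genes = paste(sort(ov), collapse = ","),
               stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (!length(rows)) return(empty)
  out <- do.call(rbind, rows)
  out$fdr_q <- stats::p.adjust(out$p, method = "BH")
  out$significant <- out$fdr_q < fdr
  out <- out[order(out$p), c("set", "a", "b", "c", "d", "odds_ratio", "p",
                             "fdr_q", "significant", "overlap_genes")]
  rownames(out) <- NULL
  class(out) <- c("enrichment_table", "data.frame")
  out
}
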