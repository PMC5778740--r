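#' Generate a 450K-like probe manifest
#'
#' Lays probes along one or more chromosomes with the spatial grammar of the
#' array: CpG islands appear as dense blocks of probes flanked by shores and
#' then shelves, separated by sparse open-sea probes. Inter-probe gaps are
#' drawn per annotation class (islands tight, sea wide), so island blocks are
#' physically compact the way real CpG islands are.
#'
#' @param n_probes total number of probes to place (>= 0).
#' @param chrom_lengths named numeric vector of chromosome lengths in bp.
#'   `NULL` sizes chromosomes automatically to fit `n_probes`.
#' @param island_fraction target fraction of probes labelled Island
#'   (achievable range roughly 0 to 0.55 given the flanking structure).
#' @param seed optional integer seed; a fixed seed gives a byte-identical
#'   manifest.
#' @return data.frame with columns `probe_id`, `chrom`, `pos`,
#'   `island_relation`, `gene_feature`, `nearest_gene`, `dnase_hs`,
#'   sorted by (chrom, pos).
#' @export
generate_manifest <- function(n_probes, chrom_lengths = NULL,
                              island_fraction = 0.3, seed = NULL) {
  if (length(n_probes) != 1 || is.na(n_probes) || n_probes < 0)
    stop("`n_probes` must be a single non-negative integer")
  n_probes <- as.integer(n_probes)
  if (!is.null(seed)) set.seed(seed)
  if (is.null(chrom_lengths)) {
    n_chrom <- max(1L, min(8L, ceiling(n_probes / 4000)))
    per <- ceiling(n_probes / n_chrom)
    chrom_lengths <- stats::setNames(rep(per * 3500 + 1e5, n_chrom),
                                     paste0("chr", seq_len(n_chrom)))
  }
  if (!length(chrom_lengths)) stop("`chrom_lengths` must be non-empty")
  if (is.null(names(chrom_lengths)))
    names(chrom_lengths) <- paste0("chr", seq_along(chrom_lengths))
  if (n_probes == 0L) {
    return(data.frame(probe_id = character(0), chrom = character(0),
                      pos = integer(0), island_relation = character(0),
                      gene_feature = character(0), nearest_gene = character(0),
                      dnase_hs = logical(0), stringsAsFactors = FALSE))
  }

  # allocate probes to chromosomes proportional to length (largest remainder)
  w <- chrom_lengths / sum(chrom_lengths)
  alloc <- floor(w * n_probes)
  rem <- n_probes - sum(alloc)
  if (rem > 0) {
    extra <- order(w * n_probes - alloc, decreasing = TRUE)[seq_len(rem)]
    alloc[extra] <- alloc[extra] + 1L
  }

  out <- vector("list", length(chrom_lengths))
  gene_counter <- 0L
  for (ci in seq_along(chrom_lengths)) {
    n_c <- alloc[ci]
    if (n_c == 0L) next
    labs <- .island_labels(n_c, island_fraction)
    gaps <- .probe_gaps(labs)
    pos <- cumsum(gaps) + sample.int(2000L, 1L)
    if (pos[n_c] > chrom_lengths[ci])
      stop("chromosome ", names(chrom_lengths)[ci], " (", chrom_lengths[ci],
           " bp) is too short for ", n_c, " probes; increase its length")
    # gene features depend on island context
    is_isl <- labs == "Island"
    gf <- character(n_c)
    gf[is_isl] <- sample(c("TSS200", "TSS1500", "Body", "Intergenic"),
                         sum(is_isl), TRUE, prob = c(0.30, 0.30, 0.25, 0.15))
    gf[!is_isl] <- sample(c("TSS200", "TSS1500", "Body", "Intergenic"),
                          sum(!is_isl), TRUE, prob = c(0.05, 0.10, 0.45, 0.40))
    # one nominal nearest gene per run of ~12-20 probes
    gene_block <- cumsum(c(TRUE, stats::runif(n_c - 1) < 1 / 15))
    genes <- sprintf("GENE%05d", gene_counter + gene_block)
    gene_counter <- gene_counter + max(gene_block)
    dnase <- stats::runif(n_c) < ifelse(is_isl, 0.40, 0.10)
    out[[ci]] <- data.frame(
      chrom = names(chrom_lengths)[ci], pos = as.integer(pos),
      island_relation = labs, gene_feature = gf, nearest_gene = genes,
      dnase_hs = dnase, stringsAsFactors = FALSE
    )
  }
  man <- do.call(rbind, out)
  man <- man[order(man$chrom, man$pos), , drop = FALSE]
  man$probe_id <- sprintf("cg%08d", sample.int(99999999L, nrow(man)))
  rownames(man) <- NULL
  man[, c("probe_id", "chrom", "pos", "island_relation", "gene_feature",
          "nearest_gene", "dnase_hs")]
}

# Island blocks of 3-8 probes wrapped Shelf|Shore|Island...|Shore|Shelf, with
# a sea run sized so the island share of each motif matches island_fraction.
.island_labels <- function(n, island_fraction) {
  if (island_fraction <= 0) return(rep("Sea", n))
  if (island_fraction > 0.55)
    stop("`island_fraction` above 0.55 is not representable with flanking shores/shelves")
  labs <- character(0)
  while (length(labs) < n) {
    k <- sample(3:8, 1L)
    block <- c("Shelf", "Shore", rep("Island", k), "Shore", "Shelf")
    s <- max(0L, as.integer(round(k / island_fraction)) - k - 4L)
    labs <- c(labs, block, rep("Sea", s))
  }
  labs[seq_len(n)]
}

.probe_gaps <- function(labs) {
  n <- length(labs)
  lo <- c(Island = 30, Shore = 150, Shelf = 400, Sea = 800)[labs]
  hi <- c(Island = 150, Shore = 700, Shelf = 1500, Sea = 6000)[labs]
  as.integer(round(stats::runif(n, lo, hi)))
}

#' Derive a gene annotation table from a manifest
#'
#' Builds one interval per distinct `nearest_gene`, spanning the probes
#' assigned to it. Useful as the gene annotation input to [nearest_gene()]
#' for synthetic manifests.
#'
#' @param manifest a probe manifest.
#' @return data.frame with `gene`, `chrom`, `start`, `end` (1-based inclusive).
#' @export
manifest_gene_table <- function(manifest) {
  keep <- !is.na(manifest$nearest_gene)
  m <- manifest[keep, , drop = FALSE]
  if (!nrow(m)) {
    return(data.frame(gene = character(0), chrom = character(0),
                      start = integer(0), end = integer(0)))
  }
  sp <- split(m, m$nearest_gene)
  out <- data.frame(
    gene = names(sp),
    chrom = vapply(sp, function(d) d$chrom[1], character(1)),
    start = vapply(sp, function(d) min(d$pos), numeric(1)),
    end = vapply(sp, function(d) max(d$pos), numeric(1)),
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  out[order(out$chrom, out$start), , drop = FALSE]
}
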