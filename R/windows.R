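#' Fisher's method for combining P values
#'
#' stat = -2 * sum(log p), referred to chi-square with 2k degrees of freedom
#' for k independent P values. Zeros are clipped to 1e-300 with a warning.
#'
#' @param pvalues numeric vector of P values in (0, 1\].
#' @return list with `stat`, `df`, `p`.
#' @export
fishers_method <- function(pvalues) {
  if (!length(pvalues)) stop("`pvalues` must be non-empty")
  if (anyNA(pvalues)) stop("`pvalues` must not contain NA")
  if (any(pvalues > 1) || any(pvalues < 0)) stop("P values must lie in [0, 1]")
  if (any(pvalues == 0)) {
    warning("P values of 0 clipped to 1e-300")
    pvalues[pvalues == 0] <- 1e-300
  }
  stat <- -2 * sum(log(pvalues))
  df <- 2L * length(pvalues)
  list(stat = stat, df = df,
       p = stats::pchisq(stat, df = df, lower.tail = FALSE))
}

#' Build 1 kb sliding windows over a sorted manifest
#'
#' One window is anchored at each distinct probe position, spanning
#' \[pos, pos + width - 1\] (1-based inclusive) and containing the anchor
#' probe and every following probe on the same chromosome within the span.
#' Probes sharing a position share one anchor. Input must already be sorted
#' by (chrom, pos); sorting is the caller's explicit step.
#'
#' @param manifest probe manifest (or `assoc_scan`) with `chrom`, `pos`,
#'   `probe_id`, sorted by (chrom, pos).
#' @param width window width in bp (default 1000).
#' @return data.frame with one row per window: `chrom`, `start`, `end`,
#'   `k` (probe count), `idx_start`, `idx_end` (row range into `manifest`)
#'   and a `probe_ids` list column.
#' @export
make_windows <- function(manifest, width = 1000) {
  if (width < 1) stop("`width` must be >= 1")
  ord <- order(manifest$chrom, manifest$pos)
  if (!identical(ord, seq_len(nrow(manifest))))
    stop("manifest must be sorted by (chrom, pos); sort it first")
  if (!nrow(manifest)) {
    return(data.frame(chrom = character(0), start = integer(0), end = integer(0),
                      k = integer(0), idx_start = integer(0), idx_end = integer(0),
                      probe_ids = I(list())))
  }
  res <- lapply(split(seq_len(nrow(manifest)), manifest$chrom), function(rows) {
    pos <- manifest$pos[rows]
    anchors <- which(!duplicated(pos))
    ends <- pos[anchors] + width - 1
    # last probe with pos <= end
    j <- findInterval(ends, pos)
    data.frame(chrom = manifest$chrom[rows[1]],
               start = pos[anchors], end = as.integer(ends),
               k = j - anchors + 1L,
               idx_start = rows[anchors], idx_end = rows[j],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out <- out[order(out$chrom, out$start), , drop = FALSE]
  out$probe_ids <- I(mapply(function(i, j) manifest$probe_id[i:j],
                            out$idx_start, out$idx_end, SIMPLIFY = FALSE))
  out
}

#' Score windows with Fisher's method
#'
#' Combines the per-probe association P values of each window. Windows
#' containing a probe with a missing P value are skipped (P = `NA`) with one
#' summary warning.
#'
#' @param windows output of [make_windows()].
#' @param probe_p numeric vector of per-probe P values aligned with the
#'   manifest rows the windows index, or named by probe id.
#' @return `windows` with `fisher_stat`, `df` and `p` columns filled.
#' @export
score_windows <- function(windows, probe_p) {
  n <- if (length(windows$idx_end)) max(windows$idx_end) else 0L
  if (length(probe_p) < n) stop("`probe_p` shorter than the probe index range")
  bad <- is.na(probe_p) | probe_p < 0 | probe_p > 1
  p_clip <- pmax(probe_p, 1e-300)
  logp <- ifelse(bad, 0, log(p_clip))
  cs <- c(0, cumsum(logp))        # zero-padded so [i] is the sum before probe i
  csbad <- c(0, cumsum(as.integer(bad)))
  i <- windows$idx_start
  j <- windows$idx_end
  sum_log <- cs[j + 1] - cs[i]
  n_bad <- csbad[j + 1] - csbad[i]
  stat <- -2 * sum_log
  df <- 2L * windows$k
  p <- stats::pchisq(stat, df = df, lower.tail = FALSE)
  skip <- n_bad > 0
  if (any(skip))
    warning(sum(skip), " window(s) skipped: member probe without a valid P value")
  windows$fisher_stat <- ifelse(skip, NA_real_, stat)
  windows$df <- df
  windows$p <- ifelse(skip, NA_real_, pmax(p, .Machine$double.xmin))
  windows
}

#' Storey q-values
#'
#' Estimates the null proportion pi0 by the smoother method: pi0(lambda) =
#' mean(p > lambda) / (1 - lambda) on the grid 0.05, 0.10, ..., 0.95, with a
#' cubic smoothing spline evaluated at the largest lambda; q-values are the
#' step-down minima of pi0 * n * p_(j) / j. With fewer than 100 P values the
#' estimate of pi0 is unstable and the procedure falls back to pi0 = 1
#' (Benjamini-Hochberg) with a warning.
#'
#' @param pvalues numeric vector of P values in \[0, 1\] (`NA` passed through).
#' @param pi0 optional fixed null proportion overriding estimation
#'   (`pi0 = 1` reproduces Benjamini-Hochberg exactly).
#' @return numeric vector of q-values, same length/order as the input.
#' @export
storey_qvalues <- function(pvalues, pi0 = NULL) {
  ok <- which(!is.na(pvalues))
  p <- pvalues[ok]
  if (!length(p)) return(pvalues)
  if (any(p < 0 | p > 1)) stop("P values must lie in [0, 1]")
  n <- length(p)
  if (is.null(pi0)) {
    if (n < 100) {
      warning("fewer than 100 P values: using pi0 = 1 (Benjamini-Hochberg)")
      pi0 <- 1
    } else {
      lam <- seq(0.05, 0.95, by = 0.05)
      pi0_l <- vapply(lam, function(l) mean(p > l) / (1 - l), numeric(1))
      fit <- stats::smooth.spline(lam, pi0_l, df = 3)
      pi0 <- stats::predict(fit, x = max(lam))$y
      pi0 <- min(pi0, 1)
      if (pi0 <= 0) {
        warning("pi0 estimate non-positive; falling back to pi0 = 1")
        pi0 <- 1
      }
    }
  }
  o <- order(p)
  ro <- integer(n)
  ro[o] <- seq_len(n)
  q_sorted <- pi0 * n * p[o] / seq_len(n)
  q_sorted <- rev(cummin(rev(pmin(q_sorted, 1))))
  out <- rep(NA_real_, length(pvalues))
  out[ok] <- q_sorted[ro]
  out
}

#' Merge significant windows into non-overlapping DMRs
#'
#' Windows with q below the threshold are unioned per chromosome wherever
#' they overlap by at least 1 bp (book-ended windows stay separate). Each
#' merged region reports the deduplicated probe union, a region P from
#' Fisher's method over that union, the best (smallest) member-window q as
#' its FDR, and a direction: hypomethylated when a strict majority of member
#' probes have case - control `delta_beta` < 0, hypermethylated for a strict
#' majority > 0, ambiguous otherwise.
#'
#' @param windows scored windows carrying a `q` column (see
#'   [score_windows()] and [storey_qvalues()]).
#' @param assoc the `assoc_scan` (or any data.frame with `probe_id`, `p`,
#'   `delta_beta`, `nearest_gene` optional) supplying per-probe values.
#' @param q_threshold FDR threshold (default 0.05).
#' @param manifest optional manifest supplying `nearest_gene` annotations.
#' @return data.frame of class `dmr_set`, one row per region: `chrom`,
#'   `start`, `end`, `n_probes`, `p`, `fdr_q`, `direction`,
#'   `source_window_count`, `nearest_genes`, plus a `probe_ids` list column.
#'   Regions are pairwise non-overlapping and sorted.
#' @export
merge_significant_windows <- function(windows, assoc, q_threshold = 0.05,
                                      manifest = NULL) {
  if (is.null(windows$q)) stop("windows must carry a `q` column")
  empty <- data.frame(chrom = character(0), start = integer(0), end = integer(0),
                      n_probes = integer(0), p = numeric(0), fdr_q = numeric(0),
                      direction = character(0), source_window_count = integer(0),
                      nearest_genes = character(0), stringsAsFactors = FALSE)
  empty$probe_ids <- I(list())
  class(empty) <- c("dmr_set", "data.frame")
  sig <- windows[!is.na(windows$q) & windows$q < q_threshold, , drop = FALSE]
  if (!nrow(sig)) return(empty)
  gr <- GenomicRanges::GRanges(sig$chrom, IRanges::IRanges(sig$start, sig$end))
  merged <- GenomicRanges::reduce(gr, min.gapwidth = 0L)
  hits <- GenomicRanges::findOverlaps(gr, merged)
  grp <- S4Vectors::subjectHits(hits)[order(S4Vectors::queryHits(hits))]
  p_by_id <- stats::setNames(assoc$p, assoc$probe_id)
  d_by_id <- stats::setNames(assoc$delta_beta, assoc$probe_id)
  gene_src <- if (!is.null(manifest) && !is.null(manifest$nearest_gene)) {
    stats::setNames(manifest$nearest_gene, manifest$probe_id)
  } else if (!is.null(assoc$nearest_gene)) {
    stats::setNames(assoc$nearest_gene, assoc$probe_id)
  } else NULL
  rows <- lapply(seq_along(merged), function(g) {
    w <- sig[grp == g, , drop = FALSE]
    ids <- unique(unlist(w$probe_ids))
    pp <- p_by_id[ids]
    fis <- fishers_method(pp[!is.na(pp)])
    dd <- d_by_id[ids]
    n_neg <- sum(dd < 0, na.rm = TRUE)
    n_pos <- sum(dd > 0, na.rm = TRUE)
    direction <- if (n_neg > n_pos) "hypomethylated"
      else if (n_pos > n_neg) "hypermethylated" else "ambiguous"
    genes <- if (is.null(gene_src)) NA_character_ else {
      gg <- unique(stats::na.omit(gene_src[ids]))
      if (length(gg)) paste(gg, collapse = ",") else NA_character_
    }
    data.frame(chrom = as.character(GenomicRanges::seqnames(merged))[g],
               start = GenomicRanges::start(merged)[g],
               end = GenomicRanges::end(merged)[g],
               n_probes = length(ids), p = fis$p, fdr_q = min(w$q),
               direction = direction, source_window_count = nrow(w),
               nearest_genes = genes, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$probe_ids <- I(lapply(seq_along(merged), function(g)
    unique(unlist(sig[grp == g, ]$probe_ids))))
  out <- out[order(out$chrom, out$start), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("dmr_set", "data.frame")
  out
}

#' @export
print.dmr_set <- function(x, ...) {
  cat("dmr_set:", nrow(x), "region(s)\n")
  if (nrow(x)) {
    tab <- table(x$direction)
    cat("  direction:", paste(names(tab), tab, sep = "=", collapse = ", "), "\n")
    NextMethod()
  }
  invisible(x)
}

#' Overlaps between two region sets
#'
#' Reports every pair of regions from `a` and `b` sharing at least 1 bp,
#' with the overlap width (1-based inclusive coordinates in, bp out).
#'
#' @param regions_a,regions_b data.frames with `chrom`, `start`, `end`.
#' @return data.frame: `a_idx`, `b_idx`, `chrom`, `overlap_bp`.
#' @export
region_overlap <- function(regions_a, regions_b) {
  empty <- data.frame(a_idx = integer(0), b_idx = integer(0),
                      chrom = character(0), overlap_bp = integer(0))
  if (!nrow(regions_a) || !nrow(regions_b)) return(empty)
  ga <- GenomicRanges::GRanges(regions_a$chrom,
                               IRanges::IRanges(regions_a$start, regions_a$end))
  gb <- GenomicRanges::GRanges(regions_b$chrom,
                               IRanges::IRanges(regions_b$start, regions_b$end))
  # the seqlevel-mismatch warning is expected when the two sets cover
  # different chromosomes
  hits <- suppressWarnings(GenomicRanges::findOverlaps(ga, gb))
  if (!length(hits)) return(empty)
  qa <- S4Vectors::queryHits(hits)
  qb <- S4Vectors::subjectHits(hits)
  ov <- suppressWarnings(GenomicRanges::pintersect(ga[qa], gb[qb]))
  data.frame(a_idx = qa, b_idx = qb,
             chrom = as.character(GenomicRanges::seqnames(ov)),
             overlap_bp = GenomicRanges::width(ov))
}
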