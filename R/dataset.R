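#' Methylation dataset container
#'
#' Bundles a beta-value matrix (probes x samples, values in \[0,1\], `NA` for
#' missing measurements), an optional detection P-value matrix of the same
#' shape, a probe manifest and a sample sheet into one object. The manifest
#' must be sorted by (chrom, pos); row order of `beta` follows the manifest
#' and column order follows the sample sheet.
#'
#' @param beta numeric matrix, probes x samples; rownames are probe ids,
#'   colnames are sample ids. Non-missing entries must lie in \[0,1\].
#' @param manifest data.frame with columns `probe_id`, `chrom`, `pos`
#'   (1-based bp), `island_relation` (Island/Shore/Shelf/Sea),
#'   `gene_feature` (TSS1500/TSS200/Body/Intergenic), `nearest_gene`,
#'   `dnase_hs` (logical).
#' @param samples data.frame with at least `sample_id`; typically also
#'   `status` ("case"/"control"), `cohort`, `age`, `sex`, `chip`,
#'   `chip_position`.
#' @param detection_p optional numeric matrix, same shape as `beta`.
#' @return an object of class `meth_set`.
#' @export
meth_set <- function(beta, manifest, samples, detection_p = NULL) {
  beta <- as.matrix(beta)
  if (!is.numeric(beta)) stop("`beta` must be a numeric matrix")
  manifest <- as.data.frame(manifest)
  samples <- as.data.frame(samples)
  required <- c("probe_id", "chrom", "pos")
  miss <- setdiff(required, names(manifest))
  if (length(miss)) stop("manifest lacks columns: ", paste(miss, collapse = ", "))
  if (nrow(beta) != nrow(manifest))
    stop("beta has ", nrow(beta), " rows but manifest has ", nrow(manifest))
  if (ncol(beta) != nrow(samples))
    stop("beta has ", ncol(beta), " columns but sample sheet has ", nrow(samples))
  if (anyDuplicated(manifest$probe_id)) stop("duplicate probe_id in manifest")
  if (is.unsorted(order(manifest$chrom, manifest$pos)) &&
      !identical(order(manifest$chrom, manifest$pos), seq_len(nrow(manifest))))
    stop("manifest must be sorted by (chrom, pos)")
  if (nrow(beta) && ncol(beta) && !all(is.na(beta))) {
    rng <- range(beta, na.rm = TRUE)
    if (rng[1] < 0 || rng[2] > 1) stop("beta values must lie in [0, 1]")
  }
  rownames(beta) <- manifest$probe_id
  colnames(beta) <- samples$sample_id
  if (!is.null(detection_p)) {
    detection_p <- as.matrix(detection_p)
    if (!identical(dim(detection_p), dim(beta)))
      stop("detection_p dimensions must match beta")
    dimnames(detection_p) <- dimnames(beta)
  }
  structure(
    list(beta = beta, detection_p = detection_p,
         manifest = manifest, samples = samples),
    class = "meth_set"
  )
}

#' @export
dim.meth_set <- function(x) dim(x$beta)

#' @export
print.meth_set <- function(x, ...) {
  cat("meth_set: ", nrow(x$beta), " probes x ", ncol(x$beta), " samples\n", sep = "")
  cat("  chromosomes: ", paste(unique(x$manifest$chrom), collapse = ", "), "\n", sep = "")
  if (!is.null(x$samples$status)) {
    tab <- table(x$samples$status)
    cat("  status: ", paste(names(tab), tab, sep = "=", collapse = ", "), "\n", sep = "")
  }
  cat("  detection P: ", if (is.null(x$detection_p)) "absent" else "present",
      "; missing beta: ", sum(is.na(x$beta)), "\n", sep = "")
  invisible(x)
}

#' Subset a methylation dataset by probe and/or sample
#'
#' @param x a `meth_set`.
#' @param probes logical/integer/character index into probes.
#' @param samples logical/integer/character index into samples.
#' @return a `meth_set` with the selected probes and samples.
#' @export
subset_meth_set <- function(x, probes = NULL, samples = NULL) {
  stopifnot(inherits(x, "meth_set"))
  pi <- if (is.null(probes)) seq_len(nrow(x$beta)) else probes
  si <- if (is.null(samples)) seq_len(ncol(x$beta)) else samples
  if (is.character(pi)) pi <- match(pi, x$manifest$probe_id)
  if (is.character(si)) si <- match(si, x$samples$sample_id)
  meth_set(
    beta = x$beta[pi, si, drop = FALSE],
    manifest = x$manifest[pi, , drop = FALSE],
    samples = x$samples[si, , drop = FALSE],
    detection_p = if (is.null(x$detection_p)) NULL else x$detection_p[pi, si, drop = FALSE]
  )
}
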