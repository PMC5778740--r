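#' Cluster probes by genomic proximity
#'
#' Greedy chaining: a probe joins the open cluster when its distance to the
#' previous probe is at most `maxgap` (boundary inclusive); otherwise a new
#' cluster starts. Clusters never span chromosomes.
#'
#' @param manifest probe manifest sorted by (chrom, pos).
#' @param maxgap maximum intra-cluster inter-probe distance in bp.
#' @return integer vector of cluster ids aligned with the manifest rows.
#' @export
cluster_probes <- function(manifest, maxgap = 1000) {
  ord <- order(manifest$chrom, manifest$pos)
  if (!identical(ord, seq_len(nrow(manifest))))
    stop("manifest must be sorted by (chrom, pos)")
  n <- nrow(manifest)
  if (!n) return(integer(0))
  new_chrom <- c(TRUE, manifest$chrom[-1] != manifest$chrom[-n])
  gap <- c(0, diff(manifest$pos))
  cumsum(new_chrom | (!new_chrom & gap > maxgap))
}

#' Per-probe case/control effect by linear regression
#'
#' For every probe, ordinary least squares of methylation (beta scale) on a
#' case indicator plus adjustment covariates (age and sex by default); the
#' returned coefficient is the covariate-adjusted case - control difference.
#' Missing beta entries are mean-imputed per probe so the fit stays a single
#' matrix solve.
#'
#' @param ds a [meth_set()].
#' @param status optional status vector; defaults to the sample sheet.
#' @param covariates sample-sheet columns to adjust for.
#' @return named numeric vector of per-probe coefficients.
#' @export
probe_effects <- function(ds, status = NULL, covariates = c("age", "sex")) {
  stopifnot(inherits(ds, "meth_set"))
  if (is.null(status)) status <- ds$samples$status
  y <- .status01(status)
  covariates <- intersect(covariates, names(ds$samples))
  keep <- vapply(covariates, function(v)
    is.numeric(ds$samples[[v]]) || length(unique(ds$samples[[v]])) > 1, logical(1))
  covariates <- covariates[keep]
  X <- if (length(covariates)) {
    stats::model.matrix(stats::as.formula(
      paste("~ case +", paste(covariates, collapse = "+"))),
      data = cbind(ds$samples, case = y))
  } else {
    stats::model.matrix(~ case, data = data.frame(case = y))
  }
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    warning("collinear covariate columns dropped from the effect design")
    X <- X[, qrX$pivot[seq_len(qrX$rank)], drop = FALSE]
  }
  B <- ds$beta
  if (anyNA(B)) {
    rm <- rowMeans(B, na.rm = TRUE)
    idx <- which(is.na(B), arr.ind = TRUE)
    B[idx] <- rm[idx[, 1]]
  }
  coefs <- t(qr.coef(qr(X), t(B)))
  stats::setNames(coefs[, "case"], ds$manifest$probe_id)
}

#' Running-median smoothing within a cluster
#'
#' Centred running median of half-width (k - 1)/2, the window truncated at
#' the cluster edges; clusters of fewer than 3 probes are returned
#' unsmoothed.
#'
#' @param coefs numeric vector of per-probe coefficients in position order.
#' @param k odd window size (default 5).
#' @return smoothed numeric vector, same length.
#' @export
smooth_cluster <- function(coefs, k = 5) {
  if (k %% 2 == 0) stop("`k` must be odd")
  n <- length(coefs)
  if (n < 3) return(coefs)
  h <- (k - 1) / 2
  vapply(seq_len(n), function(i)
    stats::median(coefs[max(1, i - h):min(n, i + h)]), numeric(1))
}

.smooth_all <- function(coefs, cluster_ids, k) {
  out <- coefs
  idx_by_cluster <- split(seq_along(coefs), cluster_ids)
  for (idx in idx_by_cluster) {
    if (length(idx) >= 3) out[idx] <- smooth_cluster(coefs[idx], k)
  }
  out
}

#' Find candidate bumps in smoothed coefficients
#'
#' Maximal runs of consecutive probes (within a cluster) whose smoothed
#' coefficient exceeds `cutoff` with a common sign (all > cutoff, or all
#' < -cutoff). Sign changes split runs.
#'
#' @param manifest sorted probe manifest.
#' @param smoothed numeric vector of smoothed coefficients aligned with the
#'   manifest.
#' @param cluster_ids integer cluster ids from [cluster_probes()].
#' @param cutoff positive threshold on |smoothed coefficient|.
#' @return data.frame: `chrom`, `start`, `end`, `n_probes`, `area`
#'   (sum of |smoothed|), `max_abs_coef`, `sign`, plus a `probe_ids` list
#'   column.
#' @export
find_bumps <- function(manifest, smoothed, cluster_ids, cutoff) {
  if (cutoff <= 0) stop("`cutoff` must be positive")
  state <- integer(length(smoothed))
  state[smoothed > cutoff] <- 1L
  state[smoothed < -cutoff] <- -1L
  state[is.na(smoothed)] <- 0L
  empty <- data.frame(chrom = character(0), start = integer(0), end = integer(0),
                      n_probes = integer(0), area = numeric(0),
                      max_abs_coef = numeric(0), sign = integer(0))
  empty$probe_ids <- I(list())
  if (!length(state) || all(state == 0L)) return(empty)
  run_break <- c(TRUE, state[-1] != state[-length(state)] |
                   cluster_ids[-1] != cluster_ids[-length(cluster_ids)])
  run_id <- cumsum(run_break)
  keep_runs <- unique(run_id[state != 0L])
  rows <- lapply(keep_runs, function(r) {
    idx <- which(run_id == r)
    data.frame(chrom = manifest$chrom[idx[1]],
               start = manifest$pos[idx[1]],
               end = manifest$pos[idx[length(idx)]],
               n_probes = length(idx),
               area = sum(abs(smoothed[idx])),
               max_abs_coef = max(abs(smoothed[idx])),
               sign = state[idx[1]],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$probe_ids <- I(lapply(keep_runs, function(r)
    manifest$probe_id[which(run_id == r)]))
  rownames(out) <- NULL
  out[order(out$chrom, out$start), , drop = FALSE]
}

#' Bootstrap family-wise error rates for candidate bumps
#'
#' Builds a null by permuting case/control labels within sex x age-tertile
#' strata, re-running the full effect/smooth/bump pipeline per replicate
#' with the same cutoff, and recording each replicate's maximum bump area.
#' `fwer` is the fraction of replicates whose null maximum reaches the
#' candidate's area; `p_boot` is the fraction of all null bump areas doing
#' so. Resolution is 1/B.
#'
#' @param ds a [meth_set()].
#' @param candidates data.frame from [find_bumps()].
#' @param cluster_ids cluster ids aligned with the dataset probes.
#' @param cutoff the cutoff used for the observed candidates.
#' @param B number of bootstrap replicates (default 1000).
#' @param k running-median window.
#' @param covariates adjustment covariates for the effect model.
#' @param seed optional integer seed.
#' @return `candidates` with `p_boot` and `fwer` columns appended.
#' @export
bootstrap_fwer <- function(ds, candidates, cluster_ids, cutoff, B = 1000,
                           k = 5, covariates = c("age", "sex"), seed = NULL) {
  if (B < 1) stop("`B` must be >= 1")
  if (B < 20) warning("small B: FWER resolution is only 1/", B)
  if (!is.null(seed)) set.seed(seed)
  if (!nrow(candidates)) {
    candidates$p_boot <- numeric(0)
    candidates$fwer <- numeric(0)
    return(candidates)
  }
  y <- .status01(ds$samples$status)
  if (anyNA(ds$beta)) {  # impute once so each replicate is a pure matrix solve
    rm <- rowMeans(ds$beta, na.rm = TRUE)
    idx <- which(is.na(ds$beta), arr.ind = TRUE)
    ds$beta[idx] <- rm[idx[, 1]]
  }
  brk <- unique(stats::quantile(ds$samples$age, c(0, 1/3, 2/3, 1)))
  age_band <- if (length(brk) > 1) {
    cut(ds$samples$age, breaks = brk, include.lowest = TRUE)
  } else factor(rep(1, length(y)))
  strata <- interaction(ds$samples$sex, age_band, drop = TRUE)
  idx_by_stratum <- split(seq_along(y), strata)
  null_max <- numeric(B)
  null_areas <- vector("list", B)
  for (b in seq_len(B)) {
    perm <- y
    for (idx in idx_by_stratum) perm[idx] <- y[sample(idx, length(idx)) ]
    co <- probe_effects(ds, status = perm, covariates = covariates)
    sm <- .smooth_all(co, cluster_ids, k)
    bumps <- find_bumps(ds$manifest, sm, cluster_ids, cutoff)
    null_areas[[b]] <- bumps$area
    null_max[b] <- if (nrow(bumps)) max(bumps$area) else 0
  }
  all_null <- unlist(null_areas)
  candidates$p_boot <- vapply(candidates$area, function(a) {
    if (!length(all_null)) 0 else mean(all_null >= a)
  }, numeric(1))
  candidates$fwer <- vapply(candidates$area, function(a) mean(null_max >= a),
                            numeric(1))
  candidates
}

#' Bump-hunting DMR search
#'
#' End-to-end wrapper: cluster probes (maxgap 1 kb), fit per-probe linear
#' case/control effects adjusted for age and sex, smooth each cluster with a
#' running median, call maximal runs beyond the cutoff (default: the 99th
#' percentile of |smoothed coefficient|) and, when `B > 0`, attach bootstrap
#' `p_boot`/`fwer` values.
#'
#' @param ds a [meth_set()].
#' @param maxgap cluster gap in bp.
#' @param k running-median window (odd).
#' @param cutoff positive threshold; `NULL` uses the 99th percentile of the
#'   smoothed |coefficient|.
#' @param B bootstrap replicates (0 skips the bootstrap).
#' @param covariates adjustment covariates.
#' @param seed optional integer seed for the bootstrap.
#' @return data.frame of class `bump_set` of candidate regions (see
#'   [find_bumps()]), with bootstrap columns when requested, plus attributes
#'   `cutoff` and `cluster_ids`.
#' @export
bumphunt <- function(ds, maxgap = 1000, k = 5, cutoff = NULL, B = 1000,
                     covariates = c("age", "sex"), seed = NULL) {
  cl <- cluster_probes(ds$manifest, maxgap)
  co <- probe_effects(ds, covariates = covariates)
  sm <- .smooth_all(co, cl, k)
  if (is.null(cutoff)) cutoff <- stats::quantile(abs(sm), 0.99, names = FALSE)
  bumps <- find_bumps(ds$manifest, sm, cl, cutoff)
  if (B > 0 && nrow(bumps)) {
    bumps <- bootstrap_fwer(ds, bumps, cl, cutoff, B = B, k = k,
                            covariates = covariates, seed = seed)
  }
  attr(bumps, "cutoff") <- cutoff
  attr(bumps, "cluster_ids") <- cl
  class(bumps) <- c("bump_set", "data.frame")
  bumps
}
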