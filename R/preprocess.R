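#' Filter probes on missingness and detection failures
#'
#' Removes any probe with more than `max_missing` missing beta values or more
#' than `max_detection_fail` samples whose detection P value exceeds
#' `detection_alpha`. The defaults (11 and 5, alpha 0.001) are the fixed
#' thresholds derived for an N = 134-per-group, 614-array study; for other
#' sample sizes [missingness_threshold()] derives a binomial-rule equivalent.
#'
#' @param ds a [meth_set()].
#' @param max_missing maximum tolerated missing values per probe.
#' @param max_detection_fail maximum tolerated detection failures per probe.
#' @param detection_alpha detection P threshold defining a failure.
#' @return list with `dataset` (filtered `meth_set`, probe order preserved)
#'   and `qc` (a `qc_report`).
#' @export
filter_probes <- function(ds, max_missing = 11, max_detection_fail = 5,
                          detection_alpha = 0.001) {
  stopifnot(inherits(ds, "meth_set"))
  if (max_missing < 0 || max_detection_fail < 0)
    stop("thresholds must be non-negative")
  n_in <- nrow(ds$beta)
  if (n_in == 0) {
    qc <- .qc_report(0L, 0L, 0L, 0L, max_missing, max_detection_fail, detection_alpha)
    return(list(dataset = ds, qc = qc))
  }
  n_miss <- rowSums(is.na(ds$beta))
  fail_miss <- n_miss > max_missing
  if (!is.null(ds$detection_p)) {
    n_det <- rowSums(ds$detection_p > detection_alpha, na.rm = TRUE)
  } else {
    n_det <- rep(0L, n_in)
  }
  fail_det <- n_det > max_detection_fail
  drop <- fail_miss | fail_det
  # a probe failing both rules is counted once, under missingness
  qc <- .qc_report(
    n_in = n_in,
    n_removed_missing = sum(fail_miss),
    n_removed_detection = sum(fail_det & !fail_miss),
    n_out = sum(!drop),
    max_missing, max_detection_fail, detection_alpha
  )
  list(dataset = subset_meth_set(ds, probes = !drop), qc = qc)
}

.qc_report <- function(n_in, n_removed_missing, n_removed_detection, n_out,
                       max_missing, max_detection_fail, detection_alpha) {
  structure(list(
    n_probes_in = as.integer(n_in),
    n_removed_missing = as.integer(n_removed_missing),
    n_removed_detection = as.integer(n_removed_detection),
    n_probes_out = as.integer(n_out),
    thresholds = list(max_missing = max_missing,
                      max_detection_fail = max_detection_fail,
                      detection_alpha = detection_alpha)
  ), class = "qc_report")
}

#' @export
print.qc_report <- function(x, ...) {
  cat("Probe QC report\n")
  cat("  probes in:            ", x$n_probes_in, "\n")
  cat("  removed (missingness):", x$n_removed_missing,
      sprintf("(> %d missing)", x$thresholds$max_missing), "\n")
  cat("  removed (detection):  ", x$n_removed_detection,
      sprintf("(> %d samples with detection P > %g)",
              x$thresholds$max_detection_fail, x$thresholds$detection_alpha), "\n")
  cat("  probes out:           ", x$n_probes_out, "\n")
  invisible(x)
}

#' Binomial missingness threshold
#'
#' Smallest count k of missing samples at which random missingness is
#' rejected: the upper-tail binomial probability P(X >= k | n, base_rate)
#' falls below `alpha` Bonferroni-corrected for the number of probes tested.
#'
#' @param n_samples samples per probe.
#' @param n_probes number of probes (Bonferroni denominator).
#' @param base_rate assumed per-entry missingness rate, in (0, 1).
#' @param alpha family-wise significance level.
#' @return integer threshold k (probes with >= k missing are non-random).
#' @export
missingness_threshold <- function(n_samples, n_probes, base_rate, alpha = 0.05) {
  if (base_rate <= 0 || base_rate >= 1)
    stop("`base_rate` must be strictly inside (0, 1)")
  if (n_samples < 1 || n_probes < 1) stop("counts must be positive")
  bound <- alpha / n_probes
  k <- 0:(n_samples + 1)
  # P(X >= k) = 1 - P(X <= k - 1)
  tail <- stats::pbinom(k - 1, n_samples, base_rate, lower.tail = FALSE)
  as.integer(k[which(tail < bound)[1]])
}

#' Covariate normalisation of beta values
#'
#' Fits, per probe, a quasi-likelihood regression with logistic link and
#' binomial variance of beta on chip, chip position, sex, age, age^2,
#' sex x age and sex x age^2 (the subset of these present in the sample
#' sheet), and replaces the probe with its overall mean plus the
#' response-scale residual, clipped to \[eps, 1 - eps\]. Missing entries stay
#' missing. Collinear design columns are dropped with a warning.
#'
#' @param ds a [meth_set()].
#' @param covariates character vector naming sample-sheet columns to correct
#'   for; `age` expands to the quadratic and sex-interaction terms.
#' @param eps clip constant applied after residualisation.
#' @return a `meth_set` with adjusted beta values.
#' @export
normalize_probes <- function(ds, covariates = c("chip", "chip_position", "sex", "age"),
                             eps = 1e-6) {
  stopifnot(inherits(ds, "meth_set"))
  covariates <- intersect(covariates, names(ds$samples))
  if (!length(covariates) || nrow(ds$beta) == 0) return(ds)
  sheet <- ds$samples
  terms <- covariates
  if (all(c("sex", "age") %in% covariates)) {
    terms <- c(setdiff(covariates, "age"),
               "age", "I(age^2)", "sex:age", "sex:I(age^2)")
  } else if ("age" %in% covariates) {
    terms <- c(setdiff(covariates, "age"), "age", "I(age^2)")
  }
  # drop factors with a single level (constant design columns)
  keep <- vapply(covariates, function(v) {
    x <- sheet[[v]]
    is.numeric(x) || length(unique(x)) > 1
  }, logical(1))
  dropped <- covariates[!keep]
  if (length(dropped))
    terms <- terms[!vapply(terms, function(tt)
      any(vapply(dropped, function(d) grepl(d, tt, fixed = TRUE), logical(1))),
      logical(1))]
  if (!length(terms)) return(ds)
  fml <- stats::as.formula(paste("~", paste(terms, collapse = " + ")))
  X <- stats::model.matrix(fml, data = sheet)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    warning("rank-deficient covariate design: dropping ",
            ncol(X) - qrX$rank, " collinear column(s)")
    X <- X[, qrX$pivot[seq_len(qrX$rank)], drop = FALSE]
  }
  beta <- ds$beta
  fam <- stats::quasibinomial()
  complete_design <- !apply(is.na(X), 1, any)
  for (p in seq_len(nrow(beta))) {
    y <- beta[p, ]
    obs <- which(!is.na(y) & complete_design)
    if (length(obs) <= ncol(X)) next
    yo <- pmin(pmax(y[obs], eps), 1 - eps)
    fit <- suppressWarnings(stats::glm.fit(X[obs, , drop = FALSE], yo, family = fam))
    adj <- mean(yo) + (yo - fit$fitted.values)
    beta[p, obs] <- pmin(pmax(adj, eps), 1 - eps)
  }
  meth_set(beta, ds$manifest, ds$samples, ds$detection_p)
}

#' Beta to M-value transform
#'
#' M = log2(beta / (1 - beta)); values are clipped to \[eps, 1 - eps\] first.
#'
#' @param beta numeric vector/matrix of beta values in \[0, 1\].
#' @param eps clip constant.
#' @return M-values with the shape of the input.
#' @export
beta_to_m <- function(beta, eps = 1e-6) {
  rng <- suppressWarnings(range(beta, na.rm = TRUE))
  if (is.finite(rng[1]) && (rng[1] < 0 || rng[2] > 1))
    stop("beta values must lie in [0, 1]")
  b <- pmin(pmax(beta, eps), 1 - eps)
  log2(b / (1 - b))
}

#' M-value to beta transform
#'
#' Inverse of [beta_to_m()]: beta = 2^M / (1 + 2^M).
#'
#' @param m numeric vector/matrix of M-values.
#' @return beta values in (0, 1) with the shape of the input.
#' @export
m_to_beta <- function(m) {
  1 / (1 + 2^(-m))
}
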