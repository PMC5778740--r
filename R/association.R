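#' Per-probe case/control logistic association
#'
#' Fits logistic regressions of case/control status on covariates (null
#' model) and on covariates plus the probe's M-value (full model), and tests
#' the methylation term by the change in deviance against chi-square with
#' 1 df. Samples with a missing M-value are dropped (complete-case per
#' probe). With perfect separation the likelihood-ratio P remains defined;
#' the Wald coefficient and SE are set to `NA` with a warning.
#'
#' @param m numeric vector of M-values for one probe.
#' @param status factor/character/logical; "case" (or `TRUE`) vs control.
#' @param covariates data.frame of per-sample adjustment covariates (default
#'   none); the scan uses cohort.
#' @param beta optional beta-value vector for descriptive group means.
#' @return one-row data.frame: `coef`, `se`, `lrt_stat`, `df`, `p`,
#'   `mean_beta_case`, `mean_beta_control`, `delta_beta`, `n_used`.
#' @export
fit_probe_association <- function(m, status, covariates = NULL, beta = NULL) {
  y <- .status01(status)
  n <- length(y)
  if (length(m) != n) stop("`m` and `status` lengths differ")
  X0 <- if (is.null(covariates) || !ncol(as.data.frame(covariates))) {
    matrix(1, n, 1)
  } else {
    stats::model.matrix(~ ., data = as.data.frame(covariates))
  }
  obs <- which(!is.na(m) & !is.na(y) & !apply(is.na(X0), 1, any))
  empty <- data.frame(coef = NA_real_, se = NA_real_, lrt_stat = NA_real_,
                      df = 1L, p = NA_real_, mean_beta_case = NA_real_,
                      mean_beta_control = NA_real_, delta_beta = NA_real_,
                      n_used = length(obs))
  if (length(obs) < 4 || length(unique(y[obs])) < 2 ||
      !stats::sd(m[obs]) > 0) {
    if (length(obs) >= 4 && length(unique(y[obs])) == 2 &&
        !is.na(stats::sd(m[obs])) && stats::sd(m[obs]) == 0) {
      # constant methylation carries no information: LRT = 0, p = 1
      empty$lrt_stat <- 0
      empty$p <- 1
    }
    return(.add_beta_means(empty, beta, y, obs))
  }
  yo <- y[obs]
  X0o <- X0[obs, , drop = FALSE]
  X1o <- cbind(X0o, m = m[obs])
  f0 <- suppressWarnings(stats::glm.fit(X0o, yo, family = stats::binomial()))
  f1 <- suppressWarnings(stats::glm.fit(X1o, yo, family = stats::binomial()))
  lrt <- max(0, f0$deviance - f1$deviance)
  p <- stats::pchisq(lrt, df = 1, lower.tail = FALSE)
  cf <- f1$coefficients[["m"]]
  se <- tryCatch({
    Xw <- X1o * sqrt(f1$weights)
    V <- chol2inv(chol(crossprod(Xw)))
    sqrt(V[ncol(X1o), ncol(X1o)])
  }, error = function(e) NA_real_)
  if (!f1$converged || !is.finite(cf) || (is.finite(se) && se > 1e3)) {
    warning("non-finite coefficient (possible perfect separation); LRT p retained")
    cf <- NA_real_
    se <- NA_real_
  }
  res <- data.frame(coef = cf, se = se, lrt_stat = lrt, df = 1L,
                    p = max(p, .Machine$double.xmin),
                    mean_beta_case = NA_real_, mean_beta_control = NA_real_,
                    delta_beta = NA_real_, n_used = length(obs))
  .add_beta_means(res, beta, y, obs)
}

.status01 <- function(status) {
  if (is.logical(status)) return(as.integer(status))
  if (is.factor(status)) status <- as.character(status)
  if (is.character(status)) {
    known <- c(case = 1L, control = 0L, non_case = 0L)
    if (!all(status %in% names(known) | is.na(status)))
      stop("status values must be 'case'/'control'")
    return(unname(known[status]))
  }
  if (is.numeric(status)) {
    if (!all(status %in% c(0, 1) | is.na(status))) stop("numeric status must be 0/1")
    return(as.integer(status))
  }
  stop("unsupported status type")
}

.add_beta_means <- function(res, beta, y, obs) {
  if (!is.null(beta) && length(obs)) {
    res$mean_beta_case <- mean(beta[obs][y[obs] == 1], na.rm = TRUE)
    res$mean_beta_control <- mean(beta[obs][y[obs] == 0], na.rm = TRUE)
    res$delta_beta <- res$mean_beta_case - res$mean_beta_control
  }
  res
}

#' Genome-wide association scan
#'
#' Runs [fit_probe_association()] for every probe of a (filtered,
#' residualised) dataset, on M-values derived from the stored beta values,
#' adjusted for the given sample-sheet covariates (cohort by default).
#' Per-probe failures are returned as flagged `NA` rows; the scan never
#' aborts. Null-model deviances are cached per missingness pattern, so the
#' usual complete-data case fits the null once.
#'
#' @param ds a [meth_set()] (beta typically residualised).
#' @param status optional status vector; defaults to `ds$samples$status`.
#' @param covariates character vector of sample-sheet column names (default
#'   "cohort"; use `character(0)` for none).
#' @return data.frame of class `assoc_scan`, one row per probe in manifest
#'   order: probe metadata plus the [fit_probe_association()] columns.
#' @export
genome_scan <- function(ds, status = NULL, covariates = "cohort") {
  stopifnot(inherits(ds, "meth_set"))
  if (is.null(status)) status <- ds$samples$status
  y <- .status01(status)
  n <- ncol(ds$beta)
  p_probes <- nrow(ds$beta)
  covariates <- intersect(covariates, names(ds$samples))
  X0 <- if (length(covariates)) {
    keep <- vapply(covariates, function(v)
      is.numeric(ds$samples[[v]]) || length(unique(ds$samples[[v]])) > 1, logical(1))
    if (any(keep)) {
      stats::model.matrix(stats::as.formula(
        paste("~", paste(covariates[keep], collapse = "+"))), data = ds$samples)
    } else matrix(1, n, 1)
  } else matrix(1, n, 1)
  out <- data.frame(
    probe_id = ds$manifest$probe_id, chrom = ds$manifest$chrom,
    pos = ds$manifest$pos,
    coef = rep(NA_real_, p_probes), se = rep(NA_real_, p_probes),
    lrt_stat = rep(NA_real_, p_probes), df = rep(1L, p_probes),
    p = rep(NA_real_, p_probes), mean_beta_case = rep(NA_real_, p_probes),
    mean_beta_control = rep(NA_real_, p_probes),
    delta_beta = rep(NA_real_, p_probes), n_used = rep(NA_integer_, p_probes),
    stringsAsFactors = FALSE
  )
  if (p_probes == 0) return(structure(out, class = c("assoc_scan", "data.frame")))
  M <- beta_to_m(ds$beta)
  fam <- stats::binomial()
  null_cache <- new.env(parent = emptyenv())
  base_ok <- !is.na(y) & !apply(is.na(X0), 1, any)
  is_case <- y == 1
  n_warn <- 0L
  for (pr in seq_len(p_probes)) {
    m <- M[pr, ]
    obs <- which(base_ok & !is.na(m))
    out$n_used[pr] <- length(obs)
    if (length(obs) < 4 || length(unique(y[obs])) < 2) next
    b <- ds$beta[pr, obs]
    out$mean_beta_case[pr] <- mean(b[is_case[obs]])
    out$mean_beta_control[pr] <- mean(b[!is_case[obs]])
    out$delta_beta[pr] <- out$mean_beta_case[pr] - out$mean_beta_control[pr]
    if (stats::sd(m[obs]) == 0) {
      out$lrt_stat[pr] <- 0
      out$p[pr] <- 1
      next
    }
    key <- paste(obs, collapse = ",")
    d0 <- null_cache[[key]]
    if (is.null(d0)) {
      f0 <- suppressWarnings(stats::glm.fit(X0[obs, , drop = FALSE], y[obs], family = fam))
      d0 <- f0$deviance
      null_cache[[key]] <- d0
    }
    X1 <- cbind(X0[obs, , drop = FALSE], m = m[obs])
    f1 <- suppressWarnings(stats::glm.fit(X1, y[obs], family = fam))
    lrt <- max(0, d0 - f1$deviance)
    out$lrt_stat[pr] <- lrt
    out$p[pr] <- max(stats::pchisq(lrt, 1, lower.tail = FALSE),
                     .Machine$double.xmin)
    cf <- f1$coefficients[["m"]]
    se <- tryCatch({
      Xw <- X1 * sqrt(f1$weights)
      sqrt(chol2inv(chol(crossprod(Xw)))[ncol(X1), ncol(X1)])
    }, error = function(e) NA_real_)
    if (!f1$converged || !is.finite(cf)) {
      n_warn <- n_warn + 1L
      cf <- NA_real_
      se <- NA_real_
    }
    out$coef[pr] <- cf
    out$se[pr] <- se
  }
  if (n_warn > 0)
    warning(n_warn, " probe(s) with non-converged/separated fits; LRT p retained")
  structure(out, class = c("assoc_scan", "data.frame"))
}

#' Genomic inflation factor
#'
#' Converts P values to chi-square (1 df) quantiles and reports the ratio of
#' their median to the expected null median statistic 0.4549.
#'
#' @param pvalues numeric vector of association P values in (0, 1\].
#' @return object of class `inflation_report`: `lambda`, `expected_median`,
#'   `n_tests`.
#' @export
inflation_lambda <- function(pvalues) {
  pvalues <- pvalues[!is.na(pvalues)]
  if (!length(pvalues)) stop("no P values supplied")
  if (any(pvalues <= 0)) {
    warning("P values <= 0 clipped to the smallest positive double")
    pvalues[pvalues <= 0] <- .Machine$double.xmin
  }
  if (any(pvalues > 1)) stop("P values must be <= 1")
  chi <- stats::qchisq(pvalues, df = 1, lower.tail = FALSE)
  expected <- stats::qchisq(0.5, df = 1, lower.tail = FALSE)  # 0.4549...
  structure(list(lambda = stats::median(chi) / expected,
                 expected_median = expected,
                 n_tests = length(pvalues)),
            class = "inflation_report")
}

#' @export
print.inflation_report <- function(x, ...) {
  cat(sprintf("Genomic inflation: lambda = %.4f (expected median chi-square %.4f, %d tests)\n",
              x$lambda, x$expected_median, x$n_tests))
  invisible(x)
}

#' Q-Q null envelope from order statistics
#'
#' Under a global null, the rank-i P value of n tests follows a
#' Beta(i, n - i + 1) law; the envelope takes its 2.5th and 97.5th centiles
#' (for `level` = 0.95) and its median as the expected line, all on the
#' -log10 scale.
#'
#' @param n number of tests (>= 1).
#' @param level envelope coverage (default 0.95).
#' @return data.frame of class `qq_band`: `rank`, `expected`, `lower`,
#'   `upper` (-log10 scale; `lower <= expected <= upper`).
#' @export
qq_band <- function(n, level = 0.95) {
  if (length(n) != 1 || is.na(n) || n < 1) stop("`n` must be a positive integer")
  i <- seq_len(n)
  a <- (1 - level) / 2
  structure(data.frame(
    rank = i,
    expected = -log10(stats::qbeta(0.5, i, n - i + 1)),
    lower = -log10(stats::qbeta(1 - a, i, n - i + 1)),
    upper = -log10(stats::qbeta(a, i, n - i + 1))
  ), class = c("qq_band", "data.frame"))
}

#' Q-Q plot of association P values with a null envelope
#'
#' @param pvalues numeric vector of P values.
#' @param level envelope coverage.
#' @param ... passed to [graphics::plot()].
#' @return invisibly, the `qq_band` used.
#' @export
plot_qq <- function(pvalues, level = 0.95, ...) {
  pvalues <- sort(pvalues[!is.na(pvalues)])
  n <- length(pvalues)
  band <- qq_band(n, level)
  obs <- -log10(pvalues)
  graphics::plot(band$expected, obs, xlab = "expected -log10(P)",
                 ylab = "observed -log10(P)", pch = 20, ...)
  graphics::polygon(c(band$expected, rev(band$expected)),
                    c(band$lower, rev(band$upper)),
                    col = grDevices::adjustcolor("grey", 0.5), border = NA)
  graphics::points(band$expected, obs, pch = 20)
  graphics::abline(0, 1, col = "white", lwd = 2)
  invisible(band)
}
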