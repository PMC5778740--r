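#' Reference-free cell-composition components (sparse-PCA selection)
#'
#' Estimates cell-type mixture axes without a reference panel: each probe is
#' standardised across samples, a rank-`K` PCA reconstruction is computed,
#' and the `t` probes best captured by the low-rank structure (smallest
#' reconstruction distance) are taken as cell-type informative. A second PCA
#' restricted to those probes yields the component scores that are regressed
#' out downstream. Missing beta entries are mean-imputed per probe for the
#' decomposition only; near-constant probes (variance < `min_var`) are
#' excluded from selection to keep the standardisation stable.
#'
#' @param beta numeric matrix, probes x samples (rownames = probe ids).
#' @param K number of components (default 5). `K = 0` returns empty scores.
#' @param t number of informative probes to select (default 500).
#' @param min_var variance floor below which probes are ignored.
#' @return object of class `celltype_components`: list with `K`, `t`,
#'   `scores` (samples x K, columns orthogonal, sign-normalised so each
#'   column's largest-magnitude loading is positive), `selected_probe_ids`,
#'   `sdev`.
#' @export
refactor_components <- function(beta, K = 5, t = 500, min_var = 1e-4) {
  beta <- as.matrix(beta)
  n <- ncol(beta)
  if (K >= n) stop("`K` must be smaller than the number of samples")
  if (K < 0) stop("`K` must be non-negative")
  if (t > nrow(beta)) stop("`t` exceeds the number of probes")
  if (K == 0) {
    return(structure(list(K = 0L, t = t,
                          scores = matrix(0, n, 0,
                                          dimnames = list(colnames(beta), NULL)),
                          selected_probe_ids = character(0), sdev = numeric(0)),
                     class = "celltype_components"))
  }
  # per-probe mean imputation, then exclusion of near-constant probes
  X <- beta
  if (anyNA(X)) {
    rm <- rowMeans(X, na.rm = TRUE)
    idx <- which(is.na(X), arr.ind = TRUE)
    X[idx] <- rm[idx[, 1]]
  }
  v <- apply(X, 1, stats::var)
  usable <- which(is.finite(v) & v >= min_var)
  if (length(usable) < t)
    stop("fewer than `t` probes with variance >= min_var")
  Z <- X[usable, , drop = FALSE]
  Z <- (Z - rowMeans(Z)) / sqrt(v[usable])
  # samples-space eigendecomposition gives the rank-K reconstruction cheaply
  C <- crossprod(Z)                      # n x n
  eig <- eigen(C, symmetric = TRUE)
  V <- eig$vectors[, seq_len(K), drop = FALSE]
  ZV <- Z %*% V
  dist2 <- rowSums(Z^2) - rowSums(ZV^2)  # squared reconstruction distance
  sel <- usable[order(dist2)[seq_len(t)]]
  Zs <- X[sel, , drop = FALSE]
  Zs <- (Zs - rowMeans(Zs)) / sqrt(apply(Zs, 1, stats::var))
  pc <- stats::prcomp(base::t(Zs), center = TRUE, scale. = FALSE)
  scores <- pc$x[, seq_len(K), drop = FALSE]
  # deterministic sign: largest-magnitude rotation loading positive
  for (j in seq_len(K)) {
    i <- which.max(abs(pc$rotation[, j]))
    if (pc$rotation[i, j] < 0) scores[, j] <- -scores[, j]
  }
  rownames(scores) <- colnames(beta)
  structure(list(
    K = as.integer(K), t = as.integer(t), scores = scores,
    selected_probe_ids = if (is.null(rownames(beta))) as.character(sel) else rownames(beta)[sel],
    sdev = pc$sdev[seq_len(K)]
  ), class = "celltype_components")
}

#' @export
print.celltype_components <- function(x, ...) {
  cat("celltype_components: K =", x$K, ", t =", x$t, "selected probes\n")
  if (x$K > 0)
    cat("  component SDs:", paste(signif(x$sdev, 4), collapse = ", "), "\n")
  invisible(x)
}

#' Regress cell-composition components out of a beta matrix
#'
#' Per probe, ordinary least squares of beta on the component scores plus an
#' intercept; the output is intercept + residual (probe means preserved),
#' clipped to \[eps, 1 - eps\]. Missing entries are excluded from each
#' probe's fit and restored as missing. Residualisation is a projection:
#' applying it twice with the same components changes nothing beyond
#' clipping.
#'
#' @param beta numeric matrix, probes x samples.
#' @param components a `celltype_components` (or a bare samples x K score
#'   matrix).
#' @param eps clip constant.
#' @return residualised beta matrix, same shape as the input.
#' @export
regress_out_components <- function(beta, components, eps = 1e-6) {
  beta <- as.matrix(beta)
  scores <- if (inherits(components, "celltype_components")) components$scores else as.matrix(components)
  if (nrow(scores) != ncol(beta))
    stop("score rows (", nrow(scores), ") must match beta columns (", ncol(beta), ")")
  if (ncol(scores) == 0) return(pmin(pmax(beta, eps), 1 - eps))
  out <- beta
  na_mask <- is.na(beta)
  complete <- !apply(na_mask, 1, any)
  Sc <- scale(scores, center = TRUE, scale = FALSE)
  if (any(complete)) {
    Y <- beta[complete, , drop = FALSE]
    B <- Y %*% Sc %*% solve(crossprod(Sc))
    out[complete, ] <- Y - B %*% base::t(Sc)
  }
  if (any(!complete)) {
    A <- cbind(1, scores)
    for (p in which(!complete)) {
      y <- beta[p, ]
      obs <- which(!is.na(y))
      if (length(obs) > ncol(A)) {
        fit <- stats::lm.fit(A[obs, , drop = FALSE], y[obs])
        cf <- fit$coefficients
        cf[is.na(cf)] <- 0
        out[p, obs] <- cf[1] + fit$residuals
      }
    }
  }
  out <- pmin(pmax(out, eps), 1 - eps)
  out[na_mask] <- NA_real_
  out
}
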