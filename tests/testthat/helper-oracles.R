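# Independent oracles used across the suite. Deliberately naive
# implementations: loops, enumeration and hand-rolled IRLS, never the
# package's own code paths.

# Logistic regression deviance by hand-rolled IRLS.
oracle_logistic_deviance <- function(X, y, tol = 1e-12, maxit = 100) {
  beta <- rep(0, ncol(X))
  for (it in seq_len(maxit)) {
    eta <- drop(X %*% beta)
    mu <- 1 / (1 + exp(-eta))
    w <- mu * (1 - mu)
    w <- pmax(w, 1e-10)
    z <- eta + (y - mu) / w
    beta_new <- solve(crossprod(X, w * X), crossprod(X, w * z))
    if (max(abs(beta_new - beta)) < tol) {
      beta <- beta_new
      break
    }
    beta <- beta_new
  }
  eta <- drop(X %*% beta)
  mu <- 1 / (1 + exp(-eta))
  -2 * sum(y * log(mu) + (1 - y) * log(1 - mu))
}

# Fisher's method by direct log-sum (loop, no vectorised shortcuts).
oracle_fisher <- function(p) {
  s <- 0
  for (x in p) s <- s + log(x)
  stat <- -2 * s
  list(stat = stat, p = stats::pchisq(stat, df = 2 * length(p), lower.tail = FALSE))
}

# Two-sided Fisher exact p by exhaustive enumeration over tables with the
# observed margins; point probabilities from log-factorials.
oracle_fisher_exact <- function(a, b, c, d) {
  m1 <- a + b; m2 <- c + d; n1 <- a + c
  lp <- function(x) {
    lchoose(m1, x) + lchoose(m2, n1 - x) - lchoose(m1 + m2, n1)
  }
  xs <- max(0, n1 - m2):min(m1, n1)
  probs <- exp(lp(xs))
  p_obs <- exp(lp(a))
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# Hypergeometric upper tail by summation.
oracle_hyper_upper <- function(k, set_size, bg_size, draw) {
  xs <- k:min(set_size, draw)
  sum(exp(lchoose(set_size, xs) + lchoose(bg_size - set_size, draw - xs) -
            lchoose(bg_size, draw)))
}

# Interval overlap by double loop (1-based inclusive).
oracle_overlap <- function(a, b) {
  out <- NULL
  for (i in seq_len(nrow(a))) {
    for (j in seq_len(nrow(b))) {
      if (a$chrom[i] != b$chrom[j]) next
      ov <- min(a$end[i], b$end[j]) - max(a$start[i], b$start[j]) + 1
      if (ov >= 1) out <- rbind(out, data.frame(a_idx = i, b_idx = j, overlap_bp = ov))
    }
  }
  if (is.null(out)) data.frame(a_idx = integer(0), b_idx = integer(0),
                               overlap_bp = integer(0)) else out
}

# Small deterministic dataset builder shared by module tests.
tiny_dataset <- function(n_probes = 60, n = 20, seed = 1) {
  set.seed(seed)
  man <- generate_manifest(n_probes, seed = seed)
  beta <- matrix(stats::runif(n_probes * n, 0.2, 0.8), n_probes, n)
  samples <- data.frame(
    sample_id = sprintf("S%02d", seq_len(n)),
    status = rep(c("case", "control"), length.out = n),
    cohort = rep(c("adult", "adolescent"), each = n / 2),
    age = stats::runif(n, 20, 60),
    sex = rep(c("F", "M"), length.out = n),
    chip = rep(c("chipA", "chipB"), each = n / 2),
    chip_position = sprintf("R%02dC01", rep(seq_len(n / 2), 2)),
    stringsAsFactors = FALSE
  )
  meth_set(beta, man, samples)
}

recovered_fraction <- function(truth, called) {
  if (!nrow(truth)) return(NA_real_)
  ov <- region_overlap(truth, called)
  if (!nrow(ov)) return(0)
  wt <- truth$end[ov$a_idx] - truth$start[ov$a_idx] + 1
  wc <- called$end[ov$b_idx] - called$start[ov$b_idx] + 1
  hit <- ov$overlap_bp >= 0.5 * wt & ov$overlap_bp >= 0.5 * wc
  length(unique(ov$a_idx[hit])) / nrow(truth)
}
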