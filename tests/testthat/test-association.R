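test_that("likelihood-ratio P matches a hand-rolled IRLS oracle", {
  set.seed(21)
  for (rep in 1:8) {
    n <- 10
    y <- c(rep(1, 5), rep(0, 5))
    m <- rnorm(n)
    cohort <- rep(c("adult", "adolescent"), 5)
    res <- fit_probe_association(m, ifelse(y == 1, "case", "control"),
                                 covariates = data.frame(cohort = cohort))
    X0 <- stats::model.matrix(~cohort)
    d0 <- oracle_logistic_deviance(X0, y)
    d1 <- oracle_logistic_deviance(cbind(X0, m), y)
    lrt <- d0 - d1
    expect_equal(res$lrt_stat, lrt, tolerance = 1e-6)
    expect_equal(res$p, pchisq(lrt, 1, lower.tail = FALSE), tolerance = 1e-6)
  }
})

test_that("constant methylation yields zero statistic and p = 1", {
  res <- fit_probe_association(rep(1.5, 12), rep(c("case", "control"), 6))
  expect_equal(res$lrt_stat, 0)
  expect_equal(res$p, 1)
})

test_that("a strong negative shift in cases gives negative coef and delta", {
  set.seed(22)
  status <- rep(c("case", "control"), each = 30)
  beta <- c(rnorm(30, 0.35, 0.03), rnorm(30, 0.55, 0.03))
  m <- beta_to_m(pmin(pmax(beta, 0.01), 0.99))
  res <- fit_probe_association(m, status, beta = beta)
  expect_lt(res$delta_beta, 0)
  expect_lt(res$p, 1e-4)
  if (is.finite(res$coef) && !is.na(res$coef)) expect_lt(res$coef, 0)
})

test_that("null P values are uniform (KS test over repeated simulation)", {
  set.seed(23)
  n <- 400
  status <- rep(c("case", "control"), each = n / 2)
  cohort <- rep(rep(c("adult", "adolescent"), each = n / 4), 2)
  p <- vapply(seq_len(1500), function(i) {
    fit_probe_association(rnorm(n), status,
                          covariates = data.frame(cohort = cohort))$p
  }, numeric(1))
  expect_gt(stats::ks.test(p, "punif")$p.value, 0.01)
})

test_that("genome_scan keys results by probe and is order-invariant", {
  ds <- tiny_dataset(n_probes = 40, n = 20, seed = 24)
  scan <- suppressWarnings(genome_scan(ds))
  expect_equal(nrow(scan), 40)
  expect_identical(scan$probe_id, ds$manifest$probe_id)
  # scan a probe-subset in different order: per-probe results identical
  idx <- c(5, 1, 9)
  sub <- subset_meth_set(ds, probes = sort(idx))
  scan2 <- suppressWarnings(genome_scan(sub))
  for (id in scan2$probe_id) {
    expect_equal(scan2$p[scan2$probe_id == id], scan$p[scan$probe_id == id])
  }
  # empty dataset scans to an empty result
  scan0 <- genome_scan(subset_meth_set(ds, probes = integer(0)))
  expect_equal(nrow(scan0), 0)
})

test_that("all-missing probes are flagged rows, not errors", {
  ds <- tiny_dataset(n_probes = 10, n = 20, seed = 25)
  ds$beta[4, ] <- NA
  scan <- suppressWarnings(genome_scan(ds))
  expect_true(is.na(scan$p[4]))
  expect_equal(sum(!is.na(scan$p)), 9)
})

test_that("lambda follows its definition and scaling property", {
  rep_ <- inflation_lambda(rep(0.5, 100))
  expect_equal(rep_$lambda, 1)
  expect_equal(rep_$expected_median, qchisq(0.5, 1, lower.tail = FALSE))
  set.seed(26)
  p <- runif(4e5)
  expect_lt(abs(inflation_lambda(p)$lambda - 1), 0.01)
  # doubling every chi-square statistic doubles lambda
  chi <- qchisq(p, 1, lower.tail = FALSE)
  p2 <- pchisq(2 * chi, 1, lower.tail = FALSE)
  expect_equal(inflation_lambda(p2)$lambda, 2 * inflation_lambda(p)$lambda,
               tolerance = 1e-8)
  # invariant under reordering
  expect_equal(inflation_lambda(sample(p))$lambda, inflation_lambda(p)$lambda)
  expect_warning(ip <- inflation_lambda(c(0, 0.5, 0.7)), "clipped")
  expect_true(is.finite(ip$lambda))
  expect_error(inflation_lambda(numeric(0)), "no P values")
})

test_that("Q-Q band follows the Beta order-statistic law", {
  b1 <- qq_band(1)
  expect_equal(b1$expected, -log10(0.5), tolerance = 1e-10)
  expect_equal(b1$lower, -log10(0.975), tolerance = 1e-10)
  expect_equal(b1$upper, -log10(0.025), tolerance = 1e-10)
  b <- qq_band(500)
  expect_true(all(b$lower <= b$expected & b$expected <= b$upper))
  expect_error(qq_band(0), "positive")
})

test_that("the 95% band covers simulated null scans", {
  set.seed(27)
  n <- 500
  band <- qq_band(n)
  # pointwise: each rank's order statistic falls inside its band 95% of the
  # time (the band is pointwise by construction)
  M <- matrix(runif(2000 * n), 2000, n)
  S <- -log10(t(apply(M, 1, sort)))
  for (i in c(1, 5, 50, 250, 500)) {
    cov_i <- mean(S[, i] >= band$lower[i] & S[, i] <= band$upper[i])
    expect_lt(abs(cov_i - 0.95), 0.02)
  }
  # jointly: scans stay inside the band at most ranks (indicators are
  # strongly correlated across ranks, so full containment is not 95%)
  inside <- rowMeans(S >= matrix(band$lower, 2000, n, byrow = TRUE) &
                       S <= matrix(band$upper, 2000, n, byrow = TRUE))
  expect_gt(mean(inside), 0.94)
  expect_gte(mean(inside >= 0.80), 0.90)
})
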