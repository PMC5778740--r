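test_that("generate_manifest places island blocks at the requested fraction", {
  man <- generate_manifest(10000, island_fraction = 0.3, seed = 1)
  expect_equal(nrow(man), 10000)
  expect_false(is.unsorted(order(man$chrom, man$pos)))
  expect_false(anyDuplicated(man$probe_id) > 0)
  expect_false(any(duplicated(man[, c("chrom", "pos")])))
  frac <- mean(man$island_relation == "Island")
  expect_lt(abs(frac - 0.3), 0.02)
  # islands are flanked by shores: every island run borders a Shore label
  runs <- rle(man$island_relation)
  isl <- which(runs$values == "Island")
  inner <- isl[isl > 1 & isl < length(runs$values)]
  expect_true(all(runs$values[inner - 1] == "Shore" | runs$values[inner + 1] == "Shore"))
})

test_that("generate_manifest handles the empty case and is deterministic", {
  expect_equal(nrow(generate_manifest(0)), 0)
  expect_error(generate_manifest(-1), "non-negative")
  m1 <- generate_manifest(500, seed = 7)
  m2 <- generate_manifest(500, seed = 7)
  expect_identical(m1, m2)
})

test_that("ID-Migraine rule classifies cases at two or more affirmative items", {
  expect_equal(classify_id_migraine(c(TRUE, TRUE, FALSE)), "case")
  expect_equal(classify_id_migraine(c(TRUE, TRUE, TRUE)), "case")
  expect_equal(classify_id_migraine(c(FALSE, FALSE, FALSE)), "non_case")
  expect_equal(classify_id_migraine(c(TRUE, FALSE, FALSE)), "non_case")
  items <- rbind(c(TRUE, FALSE, TRUE), c(FALSE, FALSE, TRUE))
  expect_equal(classify_id_migraine(items), c("case", "non_case"))
  expect_error(classify_id_migraine(c(TRUE, FALSE)), "3")
})

test_that("simulated sample sheet matches the matched case/control design", {
  s <- simulate_samples(seed = 3)
  expect_equal(nrow(s), 134)
  expect_equal(sum(s$status == "case"), 67)
  expect_equal(sum(s$status == "case" & s$cohort == "adult"), 28)
  expect_equal(sum(s$status == "case" & s$cohort == "adolescent"), 39)
  # pairing: control block mirrors case cohorts and sexes, ages within 2y
  cases <- s[s$status == "case", ]
  ctrl <- s[s$status == "control", ]
  expect_equal(ctrl$cohort, cases$cohort)
  expect_equal(ctrl$sex, cases$sex)
  expect_true(all(abs(ctrl$age - cases$age) <= 2 + 1e-9))
  # screener items consistent with status
  k <- cases$photophobia + cases$nausea + cases$disability
  expect_true(all(k >= 2))
  k0 <- ctrl$photophobia + ctrl$nausea + ctrl$disability
  expect_true(all(k0 < 2))
  expect_true(all(table(s$chip) <= 12))
})

test_that("null simulation has no case/control beta difference", {
  man <- generate_manifest(2000, seed = 5)
  sim <- simulate_dataset(man, seed = 6)
  ds <- sim$dataset
  expect_equal(nrow(sim$truth), 0)
  expect_true(all(ds$beta >= 0 & ds$beta <= 1, na.rm = TRUE))
  is_case <- ds$samples$status == "case"
  d <- rowMeans(ds$beta[, is_case], na.rm = TRUE) -
    rowMeans(ds$beta[, !is_case], na.rm = TRUE)
  expect_lt(abs(mean(d)), 3 * sd(d) / sqrt(length(d)) + 1e-3)
})

test_that("spiked regions shift case means by delta and truth is preserved", {
  man <- generate_manifest(20000, seed = 8)
  spikes <- sample_spike_regions(man, n_regions = 4, delta_beta = 0.10,
                                 n_probes = 12, seed = 9)
  sim <- simulate_dataset(man, spikes = spikes, seed = 10)
  expect_identical(sim$truth$start, spikes$start)
  expect_identical(sim$truth$end, spikes$end)
  expect_identical(sim$truth$delta_beta, spikes$delta_beta)
  ds <- sim$dataset
  is_case <- ds$samples$status == "case"
  for (r in seq_len(nrow(spikes))) {
    idx <- which(ds$manifest$chrom == spikes$chrom[r] &
                   ds$manifest$pos >= spikes$start[r] &
                   ds$manifest$pos <= spikes$end[r])
    expect_gte(length(idx), 12)
    d <- ds$beta[idx, is_case, drop = FALSE] |> rowMeans(na.rm = TRUE)
    d0 <- ds$beta[idx, !is_case, drop = FALSE] |> rowMeans(na.rm = TRUE)
    obs <- mean(d - d0)
    se <- sd(d - d0) / sqrt(length(idx))
    expect_lt(abs(obs - spikes$delta_beta[r]), 3 * se + 0.02)
  }
  # spikes outside the manifest span are rejected
  bad <- data.frame(chrom = "chrX", start = 1, end = 5000, delta_beta = 0.1)
  expect_error(simulate_dataset(man, spikes = bad, seed = 1), "outside")
})

test_that("spike placement respects span and gap constraints", {
  man <- generate_manifest(20000, seed = 8)
  sp <- sample_spike_regions(man, n_regions = 10, n_probes = 12,
                             min_span = 2500, max_span = 6000, max_gap = 900,
                             seed = 2)
  width <- sp$end - sp$start
  expect_true(all(width >= 2500 & width <= 6000))
  for (r in seq_len(nrow(sp))) {
    pos <- man$pos[man$chrom == sp$chrom[r] & man$pos >= sp$start[r] &
                     man$pos <= sp$end[r]]
    expect_true(all(diff(sort(pos)) <= 900))
  }
  expect_equal(sum(sp$delta_beta > 0), 5)  # alternating signs
})

test_that("detection failures and missingness appear at configured rates", {
  man <- generate_manifest(3000, seed = 2)
  sim <- simulate_dataset(man, detection_fail_rate = 0.01, missing_rate = 0.005,
                          seed = 4)
  ds <- sim$dataset
  expect_lt(abs(mean(ds$detection_p > 0.001) - 0.01), 0.003)
  expect_lt(abs(mean(is.na(ds$beta)) - 0.005), 0.002)
})
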