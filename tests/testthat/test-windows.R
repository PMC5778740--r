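test_that("Fisher's method matches closed forms and the log-sum oracle", {
  one <- fishers_method(0.5)
  expect_equal(one$stat, -2 * log(0.5), tolerance = 1e-10)
  expect_equal(one$p, 0.5, tolerance = 1e-12)   # k = 1 identity
  two <- fishers_method(c(0.5, 0.5))
  x <- two$stat
  expect_equal(x, -4 * log(0.5), tolerance = 1e-10)
  expect_equal(two$p, (1 + x / 2) * exp(-x / 2), tolerance = 1e-12)  # df=4 survival
  ten <- fishers_method(rep(0.01, 10))
  expect_lt(ten$p, 1e-10)
  set.seed(31)
  for (k in c(1, 3, 7, 20)) {
    p <- runif(k)
    got <- fishers_method(p)
    want <- oracle_fisher(p)
    expect_equal(got$stat, want$stat, tolerance = 1e-12)
    expect_equal(got$p, want$p, tolerance = 1e-12)
  }
  expect_error(fishers_method(numeric(0)), "non-empty")
  expect_warning(z <- fishers_method(c(0, 0.5)), "clipped")
  expect_true(z$p > 0)
})

test_that("windows anchor at each probe and never cross chromosomes", {
  man <- data.frame(
    probe_id = c("a", "b", "c", "d"),
    chrom = c("chr1", "chr1", "chr1", "chr2"),
    pos = c(100L, 500L, 1200L, 150L), stringsAsFactors = FALSE
  )
  w <- make_windows(man, width = 1000)
  expect_equal(nrow(w), 4)
  w1 <- w[w$chrom == "chr1", ]
  expect_equal(w1$start, c(100L, 500L, 1200L))
  expect_equal(w1$end, c(1099L, 1499L, 2199L))
  expect_equal(w1$k, c(2L, 2L, 1L))
  expect_identical(w1$probe_ids[[1]], c("a", "b"))
  expect_identical(w1$probe_ids[[2]], c("b", "c"))
  expect_identical(w1$probe_ids[[3]], "c")
  expect_identical(w[w$chrom == "chr2", ]$probe_ids[[1]], "d")
  # single probe
  ws <- make_windows(man[1, ])
  expect_equal(nrow(ws), 1)
  expect_equal(ws$k, 1L)
  # unsorted input is the caller's error
  expect_error(make_windows(man[c(2, 1, 3, 4), ]), "sorted")
})

test_that("duplicate positions share one anchor but both probes count", {
  man <- data.frame(probe_id = c("a", "b", "c"), chrom = "chr1",
                    pos = c(100L, 100L, 300L), stringsAsFactors = FALSE)
  w <- make_windows(man, width = 1000)
  expect_equal(nrow(w), 2)          # one anchor per distinct position
  expect_equal(w$k[1], 3L)
  expect_identical(w$probe_ids[[1]], c("a", "b", "c"))
})

test_that("window scores equal per-window Fisher recomputation", {
  man <- generate_manifest(400, seed = 32)
  set.seed(33)
  p <- runif(400)
  w <- make_windows(man)
  w <- score_windows(w, p)
  expect_equal(nrow(w), sum(!duplicated(man[, c("chrom", "pos")])))
  for (i in sample(nrow(w), 25)) {
    idx <- match(w$probe_ids[[i]], man$probe_id)
    want <- oracle_fisher(p[idx])
    expect_equal(w$fisher_stat[i], want$stat, tolerance = 1e-12 * abs(want$stat))
    expect_equal(w$p[i], want$p, tolerance = 1e-12 + 1e-12 * want$p)
    expect_equal(w$df[i], 2L * length(idx))
  }
  # single-probe window keeps its probe's p; all-ones stay at 1
  k1 <- which(w$k == 1)[1]
  if (!is.na(k1)) {
    expect_equal(w$p[k1], p[match(w$probe_ids[[k1]], man$probe_id)])
  }
  w1 <- score_windows(make_windows(man), rep(1, 400))
  expect_true(all(abs(w1$p - 1) < 1e-12))
  # a probe without a valid p skips its windows with a warning
  p2 <- p
  p2[10] <- NA
  expect_warning(wna <- score_windows(make_windows(man), p2), "skipped")
  hit <- vapply(wna$probe_ids, function(ids) man$probe_id[10] %in% ids, logical(1))
  expect_true(all(is.na(wna$p[hit])))
  expect_false(anyNA(wna$p[!hit]))
})

test_that("Storey q-values reduce to BH at pi0 = 1 and control the null", {
  set.seed(34)
  p <- runif(5000)
  expect_equal(storey_qvalues(p, pi0 = 1), p.adjust(p, "BH"), tolerance = 1e-12)
  q <- storey_qvalues(p)
  expect_false(is.unsorted(q[order(p)]))            # monotone in p
  expect_true(all(q >= 0 & q <= 1))
  # null FDR control: essentially nothing called at q < 0.05
  calls <- vapply(1:10, function(i) mean(storey_qvalues(runif(10000)) < 0.05),
                  numeric(1))
  expect_lte(mean(calls), 0.005)
  p50 <- runif(50)
  expect_warning(qs <- storey_qvalues(p50), "fewer than 100")
  expect_equal(qs, p.adjust(p50, "BH"), tolerance = 1e-12)  # BH fallback
})

test_that("significant windows merge into deduplicated, directed regions", {
  man <- data.frame(
    probe_id = sprintf("p%d", 1:12), chrom = "chr1",
    pos = c(100L, 400L, 700L, 1000L, 1300L, 1600L, 1900L, 2200L, 2500L,
            9000L, 9200L, 20000L),
    stringsAsFactors = FALSE
  )
  assoc <- data.frame(
    probe_id = man$probe_id,
    p = c(rep(1e-8, 9), 0.5, 1e-9, 0.9),
    delta_beta = c(rep(-0.1, 7), 0.1, 0.1, 0.05, 0.2, -0.3),
    stringsAsFactors = FALSE
  )
  w <- make_windows(man)
  w <- score_windows(w, assoc$p)
  w$q <- suppressWarnings(storey_qvalues(w$p))
  dm <- merge_significant_windows(w, assoc, q_threshold = 0.05)
  expect_s3_class(dm, "dmr_set")
  # overlapping windows collapse; shared probes appear once
  expect_true(all(!vapply(dm$probe_ids, anyDuplicated, integer(1))))
  expect_equal(dm$n_probes, lengths(dm$probe_ids))
  # regions non-overlapping and sorted
  if (nrow(dm) > 1) {
    expect_true(all(dm$start[-1] > dm$end[-nrow(dm)] | dm$chrom[-1] != dm$chrom[-nrow(dm)]))
  }
  # 7 of 9 probes negative in the first region -> hypomethylated
  expect_equal(dm$direction[1], "hypomethylated")
  # region p equals Fisher over the probe union
  for (g in seq_len(nrow(dm))) {
    pp <- assoc$p[match(dm$probe_ids[[g]], assoc$probe_id)]
    expect_equal(dm$p[g], oracle_fisher(pp)$p, tolerance = 1e-10)
  }
  # no significant windows -> empty, not an error
  w0 <- w
  w0$q <- 1
  expect_equal(nrow(merge_significant_windows(w0, assoc)), 0)
})

test_that("direction classification is antisymmetric", {
  man <- data.frame(probe_id = sprintf("p%d", 1:5), chrom = "chr1",
                    pos = seq(100L, 900L, by = 200L), stringsAsFactors = FALSE)
  assoc <- data.frame(probe_id = man$probe_id, p = rep(1e-10, 5),
                      delta_beta = c(-0.1, -0.2, -0.1, 0.1, -0.05))
  w <- score_windows(make_windows(man), assoc$p)
  w$q <- 0.001
  d1 <- merge_significant_windows(w, assoc)
  assoc2 <- assoc
  assoc2$delta_beta <- -assoc$delta_beta
  d2 <- merge_significant_windows(w, assoc2)
  expect_equal(d1$direction, "hypomethylated")
  expect_equal(d2$direction, "hypermethylated")
})

test_that("merging is idempotent", {
  man <- generate_manifest(300, seed = 35)
  set.seed(36)
  p <- runif(300)
  p[40:55] <- 1e-12
  assoc <- data.frame(probe_id = man$probe_id, p = p,
                      delta_beta = rnorm(300, -0.05, 0.02))
  w <- score_windows(make_windows(man), p)
  w$q <- suppressWarnings(storey_qvalues(w$p))
  dm <- merge_significant_windows(w, assoc)
  # feed the merged regions back through the overlap union: unchanged
  if (nrow(dm)) {
    again <- region_overlap(dm, dm)
    expect_equal(nrow(again), nrow(dm))   # only self-overlaps
    expect_equal(again$a_idx, again$b_idx)
  }
})

test_that("region overlap matches brute-force interval arithmetic", {
  a <- data.frame(chrom = c("chr1", "chr1", "chr2"),
                  start = c(100L, 500L, 10L), end = c(199L, 800L, 50L))
  b <- data.frame(chrom = c("chr1", "chr3"),
                  start = c(150L, 10L), end = c(299L, 90L))
  got <- region_overlap(a, b)
  expect_equal(got$overlap_bp, 50L)   # [150,199] inclusive
  expect_equal(got$a_idx, 1L)
  set.seed(37)
  ra <- data.frame(chrom = sample(c("chr1", "chr2"), 30, TRUE),
                   start = sample(1000L, 30))
  ra$end <- ra$start + sample(500L, 30)
  rb <- data.frame(chrom = sample(c("chr1", "chr2"), 30, TRUE),
                   start = sample(1000L, 30))
  rb$end <- rb$start + sample(500L, 30)
  got <- region_overlap(ra, rb)
  want <- oracle_overlap(ra, rb)
  key <- function(d) paste(d$a_idx, d$b_idx)
  expect_setequal(key(got), key(want))
  got <- got[order(got$a_idx, got$b_idx), ]
  want <- want[order(want$a_idx, want$b_idx), ]
  expect_equal(got$overlap_bp, want$overlap_bp)
  # identical lists self-overlap with full length; disjoint chroms are empty
  self <- region_overlap(ra, ra)
  full <- self[self$a_idx == self$b_idx, ]
  expect_equal(full$overlap_bp, ra$end - ra$start + 1L)
  only1 <- ra; only1$chrom <- "chr1"
  only2 <- rb; only2$chrom <- "chr2"
  expect_equal(nrow(region_overlap(only1, only2)), 0)
})
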