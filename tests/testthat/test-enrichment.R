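test_that("feature enrichment builds correct tables and exact P values", {
  man <- generate_manifest(600, seed = 51)
  set.seed(52)
  dmr_ids <- sample(man$probe_id, 40)
  tab <- feature_enrichment(dmr_ids, man, "island_relation")
  expect_s3_class(tab, "enrichment_table")
  expect_true(all(tab$a + tab$b == 40))
  expect_true(all(tab$c + tab$d == 600))
  for (i in seq_len(nrow(tab))) {
    expect_equal(tab$p[i],
                 oracle_fisher_exact(tab$a[i], tab$b[i], tab$c[i], tab$d[i]),
                 tolerance = 1e-9)
  }
  expect_error(feature_enrichment(character(0), man), "empty")
  expect_error(feature_enrichment("not_a_probe", man), "subset")
})

test_that("a uniformly drawn DMR set shows no feature enrichment", {
  man <- generate_manifest(5000, seed = 53)
  set.seed(54)
  worst <- vapply(1:20, function(i) {
    ids <- sample(man$probe_id, 100)
    min(feature_enrichment(ids, man, "island_relation")$p)
  }, numeric(1))
  # 4 levels x 20 draws: smallest p should not be extreme in a typical draw
  expect_gt(median(worst), 0.001)
})

test_that("degenerate all-in-feature tables get the infinity sentinel", {
  man <- generate_manifest(300, seed = 55)
  isl <- man$probe_id[man$island_relation == "Island"][1:10]
  tab <- feature_enrichment(isl, man, "island_relation")
  row <- tab[tab$feature == "Island", ]
  expect_equal(row$b, 0)
  expect_true(is.infinite(row$odds_ratio))
  expect_equal(row$p, oracle_fisher_exact(row$a, row$b, row$c, row$d),
               tolerance = 1e-9)
})

test_that("proportional tables give odds ratio 1 and p 1", {
  # direct check of the underlying test on the (5,5,50,50) table
  expect_equal(stats::fisher.test(matrix(c(5, 5, 50, 50), 2))$p.value, 1)
  expect_equal((5 * 50) / (5 * 50), 1)
})

test_that("Fisher exact matches exhaustive enumeration over small margins", {
  set.seed(56)
  for (i in 1:40) {
    a <- sample(0:12, 1); b <- sample(0:12, 1)
    c_ <- sample(0:15, 1); d <- sample(0:15, 1)
    if ((a + b) == 0 || (c_ + d) == 0) next
    got <- stats::fisher.test(matrix(c(a, b, c_, d), 2))$p.value
    expect_equal(got, oracle_fisher_exact(a, b, c_, d), tolerance = 1e-9,
                 label = sprintf("table(%d,%d,%d,%d)", a, b, c_, d))
  }
})

test_that("nearest gene returns overlaps, minimum-distance genes and ties", {
  genes <- data.frame(gene = c("G1", "G2", "G3"),
                      chrom = c("chr1", "chr1", "chr2"),
                      start = c(100L, 1000L, 50L), end = c(300L, 1200L, 80L))
  regions <- data.frame(chrom = c("chr1", "chr1", "chr1", "chr9"),
                        start = c(150L, 400L, 650L, 5L),
                        end = c(250L, 500L, 650L, 10L))
  expect_warning(got <- nearest_gene(regions, genes), "absent")
  expect_equal(got[[1]], "G1")              # inside the gene body
  expect_equal(got[[2]], "G1")              # 100 bp to G1 vs 500 to G2
  expect_setequal(got[[3]], c("G1", "G2"))  # equidistant tie: both
  expect_true(is.na(got[[4]]))              # chromosome absent
  # empty annotation annotates everything NA
  none <- nearest_gene(regions, genes[0, ])
  expect_true(all(vapply(none, function(x) all(is.na(x)), logical(1))))
})

test_that("gene-set enrichment reproduces the exact hypergeometric example", {
  bg <- sprintf("g%03d", 1:100)
  sets <- list(SET10 = bg[1:10])
  res <- geneset_enrichment(bg[1:3], sets, bg, min_overlap = 2)
  expect_equal(res$p, 120 / 161700, tolerance = 1e-12)
  expect_equal(res$a, 3)
  expect_equal(res$overlap_genes, "g001,g002,g003")
  # oracle agreement over random configurations
  set.seed(57)
  for (i in 1:20) {
    m <- sample(3:30, 1)
    sets_i <- list(S = sample(bg, m))
    gl <- sample(bg, sample(3:20, 1))
    res_i <- geneset_enrichment(gl, sets_i, bg, min_overlap = 0)
    k <- length(intersect(gl, sets_i$S))
    if (nrow(res_i)) {
      expect_equal(res_i$p, oracle_hyper_upper(k, m, 100, length(gl)),
                   tolerance = 1e-10)
    }
  }
})

test_that("gene sets below the minimum overlap are excluded", {
  bg <- sprintf("g%03d", 1:50)
  sets <- list(A = bg[1:10], B = bg[41:50])
  res <- geneset_enrichment(bg[c(1, 2, 41)], sets, bg, min_overlap = 2)
  expect_equal(res$set, "A")                 # B overlaps only once
  res0 <- geneset_enrichment(bg[30], sets, bg, min_overlap = 2)
  expect_equal(nrow(res0), 0)
  expect_equal(nrow(geneset_enrichment(bg[1], list(), bg)), 0)
  expect_error(geneset_enrichment("zzz", sets, bg), "must contain")
})

test_that("GMT round-trips and tolerates trailing tabs", {
  path <- tempfile(fileext = ".gmt")
  writeLines(c("SET1\tfirst set\tg1\tg2\tg3",
               "SET2\tsecond set\tg4\tg5\t\t"), path)
  sets <- read_gmt(path)
  expect_equal(names(sets), c("SET1", "SET2"))
  expect_equal(as.character(sets$SET2), c("g4", "g5"))  # no phantom genes
  expect_equal(attr(sets$SET1, "description"), "first set")
  out <- tempfile(fileext = ".gmt")
  write_gmt(sets, out)
  expect_equal(lapply(read_gmt(out), as.character),
               lapply(sets, as.character))
  bad <- tempfile()
  writeLines("onlyname", bad)
  expect_error(read_gmt(bad), "malformed")
})
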