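cfg_crc <- preprocess_config("crc", jitter = FALSE)

test_that("config presets carry the published thresholds and validate", {
  expect_equal(cfg_crc$min_lib, 2000)
  expect_equal(cfg_crc$max_lib, 50000)
  expect_equal(cfg_crc$min_gene_variance, 3)
  cc <- preprocess_config("cc")
  expect_equal(cc$min_lib, 40000)
  expect_equal(cc$max_lib, 150000)
  expect_equal(cc$min_nonzero_cells, 20L)
  expect_equal(cc$dag_axis_len, 0.1)
  expect_error(preprocess_config(min_lib = 10, max_lib = 5), "min_lib")
})

test_that("library-size bounds are inclusive", {
  tot <- c(1999, 2000, 50000, 50001)
  m <- toy_matrix(nascent = matrix(tot - 1000, 1), mature = matrix(rep(1000, 4), 1))
  out <- filter_cells_by_library(m, cfg_crc)
  expect_identical(out$cell_ids, m$cell_ids[2:3])
  # all inside -> identity
  m2 <- toy_matrix(matrix(c(3000, 4000), 1), matrix(c(10, 10), 1))
  expect_identical(filter_cells_by_library(m2, cfg_crc)$cell_ids, m2$cell_ids)
  # all outside -> explicit error
  m3 <- toy_matrix(matrix(c(10, 20), 1), matrix(c(1, 2), 1))
  expect_error(filter_cells_by_library(m3, cfg_crc), "empty result")
})

test_that("cell filter equals brute-force per-cell evaluation on a random fixture", {
  set.seed(10)
  n <- matrix(rpois(50, 800), 5, 10)
  m <- matrix(rpois(50, 600), 5, 10)
  bm <- toy_matrix(n, m)
  cfg <- preprocess_config(min_lib = 6500, max_lib = 7500)
  keep <- vapply(seq_len(10), function(j) {
    tot <- sum(n[, j]) + sum(m[, j]); tot >= 6500 && tot <= 7500
  }, logical(1))
  expect_identical(filter_cells_by_library(bm, cfg)$cell_ids, bm$cell_ids[keep])
})

test_that("gene variance filter uses sample variance and the printed threshold", {
  n <- rbind(rep(2, 4), c(0, 0, 3, 3), rep(0, 4))
  m <- rbind(rep(3, 4), c(0, 0, 3, 3), c(5, 5, 5, 5))
  bm <- toy_matrix(n, m)
  # totals per gene: {5,5,5,5} var 0; {0,0,6,6} var 12; {5,5,5,5} var 0
  out <- filter_genes_by_variance(bm, 3)
  expect_identical(out$gene_ids, "gene2")
  expect_identical(filter_genes_by_variance(bm, 0)$gene_ids, bm$gene_ids)
  expect_equal(var(c(0, 0, 6, 6)), 12)   # the convention the filter relies on
})

test_that("library normalization equalizes totals to the viable-cell mean", {
  n <- matrix(c(30, 100), 1); m <- matrix(c(70, 200), 1)
  bm <- toy_matrix(n, m)                  # totals 100, 300
  out <- library_normalize(bm)
  expect_equal(unname(cell_totals(out)), c(200, 200))
  # single cell unchanged
  one <- toy_matrix(matrix(5, 1), matrix(7, 1))
  expect_equal(library_normalize(one)$nascent, one$nascent)
  # element-wise contract on a 5-cell fixture
  set.seed(11)
  n5 <- matrix(rpois(15, 20), 3, 5); m5 <- matrix(rpois(15, 30), 3, 5)
  bm5 <- toy_matrix(n5, m5)
  tot <- colSums(n5) + colSums(m5)
  out5 <- library_normalize(bm5)
  expect_equal(unname(out5$nascent), sweep(n5, 2, mean(tot) / tot, `*`))
  expect_equal(unname(out5$mature), sweep(m5, 2, mean(tot) / tot, `*`))
})

test_that("pre-fit gene gate applies mean and non-zero-cell thresholds in both phenotypes", {
  ph <- rep(c("a", "b"), each = 30)
  mk <- function(mean_a, mean_b) c(rep(mean_a, 30), rep(mean_b, 30))
  n <- rbind(mk(3, 2), mk(3, 3), mk(6, 6))
  m <- rbind(mk(3, 2), mk(3, 3), mk(6, 6))   # totals: {6,4}, {6,6}, {12,12}
  bm <- toy_matrix(n, m, phenotype = ph)
  cfg <- preprocess_config()
  expect_identical(prefit_gene_gate(bm, cfg, c("a", "b")),
                   c("gene2", "gene3"))
  expect_error(prefit_gene_gate(bm, cfg, c("a", "zz")), "unknown phenotype")

  # non-zero-cell gate: gene with 25 vs 19 non-zero cells fails at 20
  n2 <- rbind(c(rep(2, 25), rep(0, 5), rep(2, 19), rep(0, 11)))
  m2 <- n2 * 5
  bm2 <- toy_matrix(n2, m2, phenotype = ph)
  cfg20 <- preprocess_config(min_nonzero_cells = 20)
  expect_identical(prefit_gene_gate(bm2, cfg20, c("a", "b")), character(0))
  expect_identical(prefit_gene_gate(bm2, preprocess_config(), c("a", "b")),
                   "gene1")
})

test_that("pre-fit gate equals brute-force evaluation on a randomized fixture", {
  set.seed(12)
  ph <- rep(c("a", "b"), each = 40)
  n <- matrix(rpois(50 * 80, 4), 50, 80)
  m <- matrix(rpois(50 * 80, 4), 50, 80)
  bm <- toy_matrix(n, m, phenotype = ph)
  cfg <- preprocess_config(min_nonzero_cells = 35)
  tot <- n + m
  brute <- bm$gene_ids[vapply(seq_len(50), function(g) {
    a <- tot[g, ph == "a"]; b <- tot[g, ph == "b"]
    mean(a) > 5 && mean(b) > 5 && sum(a > 0) >= 35 && sum(b > 0) >= 35
  }, logical(1))]
  expect_identical(prefit_gene_gate(bm, cfg, c("a", "b")), brute)
})

test_that("gene cloud pipeline: zero removal, min-max scaling, joint-outlier trim", {
  # zero-cell removal happens before normalization
  n <- matrix(c(0, 2, 4, 6, 8, 10, 12, 14), 1)
  m <- matrix(c(50, 10, 20, 30, 40, 50, 60, 70), 1)
  bm <- toy_matrix(n, m, phenotype = rep("a", 8))
  cl <- build_gene_cloud(bm, "gene1", "a", preprocess_config(jitter = FALSE))
  expect_equal(cl$n_raw_cells, 8L)
  # the zero-nascent cell goes first; the perfectly correlated joint maximum
  # is then trimmed by the 99th-percentile rule
  expect_equal(cl$n_retained, 6L)
  expect_true(all(cl$points >= 0 & cl$points <= 1))
  expect_equal(sort(cl$points[, "nascent"]), (0:5) / 6)

  # explicit min-max: {1,2,3} -> {0, 0.5, 1}, needs >= 6 points so double up
  n2 <- matrix(rep(c(1, 2, 3), 2), 1)
  m2 <- matrix(rep(c(10, 20, 30), 2), 1)
  bm2 <- toy_matrix(n2, m2, phenotype = rep("a", 6))
  cl2 <- build_gene_cloud(bm2, "gene1", "a", preprocess_config(jitter = FALSE))
  expect_equal(sort(unique(cl2$points[, "nascent"])), c(0, 0.5, 1))
  expect_equal(sort(unique(cl2$points[, "mature"])), c(0, 0.5, 1))
})

test_that("joint outlier removal drops only cells extreme on both axes", {
  set.seed(13)
  base_x <- runif(196, 10, 60); base_y <- runif(196, 10, 60)
  # two joint extremes (top-2 on both axes), one x-only and one y-only extreme
  x <- c(base_x, 200, 210, 150, 15)
  y <- c(base_y, 190, 205, 20, 150)
  bm <- toy_matrix(matrix(y, 1), matrix(x, 1), phenotype = rep("a", 200))
  cfg <- preprocess_config(jitter = FALSE)
  cl <- build_gene_cloud(bm, "gene1", "a", cfg)
  # independent evaluation with the declared (type 7) percentile convention
  xn <- (x - min(x)) / diff(range(x)); yn <- (y - min(y)) / diff(range(y))
  qx <- quantile(xn, 0.99, type = 7, names = FALSE)
  qy <- quantile(yn, 0.99, type = 7, names = FALSE)
  keep <- !(xn > qx & yn > qy)
  expect_equal(cl$n_retained, sum(keep))
  expect_equal(cl$points[, "mature"], unname(xn[keep]))
  # both planted joint extremes removed, single-axis extremes survived
  expect_false(any(keep[197:198]))
  expect_equal(cl$n_retained, 198L)
  expect_true(any(abs(cl$points[, "mature"] - xn[199]) < 1e-12))
  expect_true(any(abs(cl$points[, "nascent"] - yn[200]) < 1e-12))
})

test_that("jitter is seeded, bounded by range/50 and kept apart from the points", {
  set.seed(14)
  n <- matrix(rpois(50, 30) + 1, 1); m <- matrix(rpois(50, 40) + 1, 1)
  bm <- toy_matrix(n, m, phenotype = rep("a", 50))
  cfg <- preprocess_config(jitter = TRUE, seed = 42)
  c1 <- build_gene_cloud(bm, "gene1", "a", cfg)
  c2 <- build_gene_cloud(bm, "gene1", "a", cfg)
  expect_identical(c1$points_jittered, c2$points_jittered)
  expect_false(identical(c1$points, c1$points_jittered))
  expect_lte(max(abs(c1$points - c1$points_jittered)), 1 / 50 + 1e-12)
  expect_null(build_gene_cloud(bm, "gene1", "a",
                               preprocess_config(jitter = FALSE))$points_jittered)
})

test_that("too few usable cells is an explicit error", {
  bm <- toy_matrix(matrix(c(1, 2, 3, 0, 0, 0, 0), 1),
                   matrix(rep(5, 7), 1), phenotype = rep("a", 7))
  expect_error(build_gene_cloud(bm, "gene1", "a", cfg_crc),
               "insufficient points")
})

test_that("knn smoothing: k = 1 is the identity and smoothing contracts the cloud", {
  set.seed(15)
  ph <- rep(c("a", "b"), each = 15)
  n <- matrix(rpois(2 * 30, 20), 2, 30); m <- matrix(rpois(2 * 30, 20), 2, 30)
  bm <- toy_matrix(n, m, phenotype = ph)
  s1 <- knn_smooth(bm, 1, "separate")
  expect_equal(s1$nascent, bm$nascent)
  expect_error(knn_smooth(bm, 16, "separate"), "exceeds pool size")
  # two identical cells, k = 2 -> unchanged
  twin <- toy_matrix(matrix(c(4, 4), 1), matrix(c(6, 6), 1),
                     phenotype = c("a", "a"))
  expect_equal(knn_smooth(twin, 2, "together")$mature, twin$mature)
  # strong smoothing shrinks per-gene variance
  sm <- knn_smooth(bm, 10, "together")
  v0 <- sum(apply(rbind(bm$nascent, bm$mature), 1, var))
  v1 <- sum(apply(rbind(sm$nascent, sm$mature), 1, var))
  expect_lt(v1, v0)
})

test_that("full preprocessing is deterministic and purely subsetting", {
  sim <- simulate_dataset(n_genes_per_scenario = 3, n_batches = 2,
                          n_cells = 40, count_scale = 200, seed = 9)
  p1 <- preprocess(sim$matrix, cfg_crc)
  p2 <- preprocess(sim$matrix, cfg_crc)
  expect_identical(p1$matrix$nascent, p2$matrix$nascent)
  expect_true(all(p1$matrix$cell_ids %in% sim$matrix$cell_ids))
  expect_true(all(p1$matrix$gene_ids %in% sim$matrix$gene_ids))
  tot <- cell_totals(p1$matrix)
  expect_equal(max(abs(tot - mean(tot))), 0, tolerance = 1e-9)
})
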