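make_dt <- function(lfc, fdr, mean_1, mean_2 = mean_1,
                    gene = paste0("g", seq_along(lfc))) {
  dt <- data.frame(gene = gene, lfc = lfc, pvalue = fdr, fdr = fdr,
                   mean_1 = mean_1, mean_2 = mean_2, stringsAsFactors = FALSE)
  class(dt) <- c("differential_table", class(dt))
  dt
}

test_that("builtin rank-sum DE computes fold changes and flat-gene p-values", {
  ph <- rep(c("a", "b"), each = 20)
  set.seed(20)
  v <- rpois(20, 10) + 1
  flat <- c(v, v)                         # identical distributions -> lfc 0
  up <- c(rep(40, 20), rep(10, 20))       # means {40, 10} -> lfc 2
  noisy <- rpois(40, 15)
  bm <- toy_matrix(rbind(flat, up, noisy) / 2, rbind(flat, up, noisy) / 2,
                   phenotype = ph)
  dt <- compute_builtin_de(bm, c("a", "b"))
  expect_equal(dt$lfc[1], 0)
  expect_gt(dt$pvalue[1], 0.99)
  expect_equal(dt$lfc[2], 2)
  expect_lt(dt$fdr[2], 1e-6)
  expect_error(compute_builtin_de(toy_matrix(matrix(1, 1, 3), matrix(1, 1, 3),
                                             phenotype = c("a", "a", "b")),
                                  c("a", "b")),
               "at least 3 cells")
})

test_that("planted fold-change genes get the smallest adjusted p-values", {
  set.seed(21)
  ph <- rep(c("a", "b"), each = 25)
  base <- matrix(rpois(100 * 50, 20), 100, 50)
  base[1:10, ph == "a"] <- matrix(rpois(10 * 25, 80), 10, 25)  # 4-fold up
  bm <- toy_matrix(base / 2, base / 2, phenotype = ph)
  dt <- compute_builtin_de(bm, c("a", "b"))
  expect_setequal(order(dt$fdr)[1:10], 1:10)
})

test_that("DEG gates are inclusive exactly as printed", {
  dt <- make_dt(lfc = c(1.0, 0.99, -1.5, 2, 1.2),
                fdr = c(0.01, 0.001, 0.0005, 0.011, 0.002),
                mean_1 = c(11, 100, 50, 60, 10),
                mean_2 = c(2, 3, 4, 5, 10))
  expect_setequal(call_degs(dt), c("g1", "g3"))
  # g2 fails |lfc| < 1, g4 fails fdr > 0.01, g5 fails mean not > 10
  expect_setequal(call_degs(dt, mean_mode = "both"), character(0))
})

test_that("DEG calls equal brute-force row evaluation on a constructed table", {
  set.seed(22)
  dt <- make_dt(lfc = runif(50, -2, 2), fdr = runif(50, 0, 0.05),
                mean_1 = runif(50, 0, 30), mean_2 = runif(50, 0, 30))
  brute <- dt$gene[abs(dt$lfc) >= 1 & dt$fdr <= 0.01 &
                     (dt$mean_1 > 10 | dt$mean_2 > 10)]
  expect_identical(call_degs(dt), brute)
})

test_that("DAG gates: theta window, axis length in both fits, mean, |LFC| < 1", {
  st <- data.frame(
    gene = paste0("g", 1:5),
    theta = c(170, 45, 45, 45, 45),
    major_len_1 = c(0.2, 0.2, 0.005, 0.2, 0.2),
    major_len_2 = c(0.2, 0.2, 0.2, 0.005, 0.2),
    stringsAsFactors = FALSE
  )
  dt <- make_dt(lfc = c(0.3, 0.3, 0.3, 0.3, 1.0),
                fdr = rep(0.5, 5), mean_1 = rep(50, 5))
  out <- call_dags(st, dt, axis_len_min = 0.01)
  expect_identical(out, "g2")             # g1: theta 170; g3/g4: one short axis; g5: |lfc| >= 1
})

test_that("DAG calls equal brute-force evaluation and never overlap DEGs", {
  set.seed(23)
  n <- 50
  st <- data.frame(gene = paste0("g", 1:n),
                   theta = runif(n, 0, 180),
                   major_len_1 = runif(n, 0, 0.3),
                   major_len_2 = runif(n, 0, 0.3),
                   stringsAsFactors = FALSE)
  dt <- make_dt(lfc = runif(n, -2, 2), fdr = runif(n, 0, 0.02),
                mean_1 = runif(n, 0, 40), mean_2 = runif(n, 0, 40))
  dags <- call_dags(st, dt, axis_len_min = 0.1)
  brute <- st$gene[st$major_len_1 > 0.1 & st$major_len_2 > 0.1 &
                     st$theta > 10 & st$theta < 160 &
                     (dt$mean_1 > 10 | dt$mean_2 > 10) & abs(dt$lfc) < 1]
  expect_identical(dags, brute)
  expect_length(intersect(dags, call_degs(dt)), 0)
})

test_that("recurrence is the strict intersection across runs", {
  expect_setequal(recurrent(list(c("A", "B", "C"), c("B", "C"), c("B", "C", "D"))),
                  c("B", "C"))
  expect_length(recurrent(list(c("A", "B"), character(0), c("A"))), 0)
  expect_error(recurrent(list(c("A"))), "at least 2 runs")
  set.seed(24)
  sets <- lapply(1:5, function(i) sample(letters, 12))
  expect_setequal(recurrent(sets), Reduce(intersect, sets))
})

test_that("gene rank is the minimal semi-axis ratio, sorted descending", {
  fits <- data.frame(
    gene = c("gA", "gA", "gA", "gB", "gC", "gC"),
    run = c("b1", "b2", "b3", "b1", "b1", "b2"),
    phenotype = "p",
    semi_major = c(3.0, 1.2, 2.5, 2.0, 1.0, 4.0),
    semi_minor = c(1.0, 1.0, 1.0, 0.5, 1.0, 1.0),
    stringsAsFactors = FALSE
  )
  rk <- rank_dags(fits)
  expect_equal(rk$rank_value[rk$gene == "gA"], 1.2)  # min over fits
  expect_equal(rk$rank_value[rk$gene == "gC"], 1.0)  # circle lands last
  expect_identical(rk$gene, c("gB", "gA", "gC"))
  set.seed(25)
  big <- data.frame(gene = rep(paste0("g", 1:20), each = 4),
                    semi_major = runif(80, 1, 5), semi_minor = runif(80, 0.2, 1))
  rk2 <- rank_dags(big)
  brute <- sort(tapply(big$semi_major / big$semi_minor, big$gene, min),
                decreasing = TRUE)
  expect_equal(rk2$rank_value, as.numeric(brute))
  expect_identical(rk2$gene, names(brute))
})

test_that("theta rank-sum test behaves at the extremes", {
  th <- c(12, 30, 55, 80, 110, 140)
  same <- wilcoxon_theta(th, th)
  expect_gt(same$p_value, 0.9)
  expect_lt(same$ci95[1], 0); expect_gt(same$ci95[2], 0)
  expect_identical(wilcoxon_theta(c(1, 2, 3), c(4, 5, 6))$u_statistic, 0)
  set.seed(26)
  g1 <- runif(50, 0, 40); g2 <- g1 + 20
  shifted <- wilcoxon_theta(g1, g2)
  expect_lt(shifted$p_value, 1e-6)
  expect_lt(shifted$ci95[2], 0)
  expect_error(wilcoxon_theta(numeric(0), th), "non-empty")
})

test_that("rank-sum test matches the exhaustive-permutation oracle for small groups", {
  set.seed(27)
  for (i in 1:15) {
    n1 <- sample(3:8, 1); n2 <- sample(3:8, 1)
    x <- runif(n1, 0, 180); y <- runif(n2, 0, 180)
    mine <- wilcoxon_theta(x, y)
    oracle <- perm_wilcox(x, y)
    expect_equal(mine$u_statistic, oracle$u)
    expect_equal(mine$p_value, oracle$p, tolerance = 1e-12)
  }
})

test_that("GSEA rank exports follow the printed metrics and ordering", {
  dt <- make_dt(lfc = c(2, -1, 0.5), fdr = c(0, 0.099, 0.9), mean_1 = rep(20, 3))
  st <- data.frame(gene = dt$gene, theta = c(90, 45, 170), stringsAsFactors = FALSE)
  ranks <- data.frame(gene = dt$gene, rank_value = c(2, 3, 1.5),
                      stringsAsFactors = FALSE)
  d <- tempfile()
  paths <- gsea_rank_export(st, dt, ranks, d)
  de <- read.table(paths[["de"]], sep = "\t")
  # fdr 0, lfc 2 -> -log10(0.001) * 2 = 6; fdr 0.099, lfc -1 -> -1
  expect_equal(de$V2[de$V1 == "g1"], 6, tolerance = 1e-9)
  expect_equal(de$V2[de$V1 == "g2"], -1, tolerance = 1e-9)
  expect_true(!is.unsorted(rev(de$V2)))
  dag <- read.table(paths[["dag"]], sep = "\t")
  # theta 90 deg = 0.5 pi-radians, rank 2 -> metric 1
  expect_equal(dag$V2[dag$V1 == "g1"], 1, tolerance = 1e-9)
  expect_true(!is.unsorted(rev(dag$V2)))
  # file ordering equals brute-force metric sort
  brute <- (st$theta / 180) * ranks$rank_value
  expect_identical(dag$V1, dt$gene[order(-brute)])
})

test_that("external DE tables are validated on read", {
  d <- tempfile(fileext = ".tsv")
  write.table(data.frame(gene = "g1", lfc = 1, padj = 0.005,
                         mean_1 = 20, mean_2 = 3),
              d, sep = "\t", quote = FALSE, row.names = FALSE)
  dt <- read_de_table(d)
  expect_equal(dt$fdr, 0.005)             # padj accepted as fdr
  expect_identical(attr(dt, "source"), "external")
  bad <- tempfile(fileext = ".tsv")
  write.table(data.frame(gene = "g1", lfc = 1), bad, sep = "\t",
              quote = FALSE, row.names = FALSE)
  expect_error(read_de_table(bad), "format error")
})
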