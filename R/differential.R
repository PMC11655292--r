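#' Built-in rank-sum differential expression (fallback)
#'
#' A download-free fallback DE engine: per gene, the log2 fold change of
#' mean library-normalized totals between the two phenotypes, a two-sided
#' Wilcoxon rank-sum p-value on the per-cell totals and Benjamini-Hochberg
#' adjustment. It is a fallback, not a replacement for a dedicated
#' single-cell DE engine; externally produced tables (e.g. DESeq2-style)
#' are the preferred input and can be read with [read_de_table()].
#'
#' @param m a library-normalized `bimodal_matrix`.
#' @param phenotype_pair two phenotype labels; fold change is phenotype 1
#'   over phenotype 2.
#' @return a `differential_table`: data.frame with `gene`, `lfc`, `pvalue`,
#'   `fdr`, `mean_1`, `mean_2` and attribute `source = "builtin"`.
#' @export
compute_builtin_de <- function(m, phenotype_pair) {
  stopifnot(inherits(m, "bimodal_matrix"), length(phenotype_pair) == 2L)
  c1 <- m$phenotype == phenotype_pair[1L]
  c2 <- m$phenotype == phenotype_pair[2L]
  if (sum(c1) < 3L || sum(c2) < 3L)
    stop("each phenotype needs at least 3 cells for the rank-sum fallback")
  tot <- m$nascent + m$mature
  t1 <- tot[, c1, drop = FALSE]
  t2 <- tot[, c2, drop = FALSE]
  m1 <- rowMeans(t1); m2 <- rowMeans(t2)
  lfc <- log2(m1 / m2)
  p <- vapply(seq_len(nrow(tot)), function(i) {
    suppressWarnings(stats::wilcox.test(t1[i, ], t2[i, ])$p.value)
  }, numeric(1))
  dt <- data.frame(gene = m$gene_ids, lfc = lfc, pvalue = p,
                   fdr = stats::p.adjust(p, "BH"),
                   mean_1 = m1, mean_2 = m2, stringsAsFactors = FALSE)
  attr(dt, "source") <- "builtin"
  class(dt) <- c("differential_table", class(dt))
  dt
}

#' Read an external differential-expression table
#'
#' Delimited file with header columns `gene`, `lfc`, `fdr` (or `padj`),
#' `mean_1`, `mean_2`.
#'
#' @param path file path.
#' @param sep field separator (default tab).
#' @return a `differential_table` with attribute `source = "external"`.
#' @export
read_de_table <- function(path, sep = "\t") {
  dt <- utils::read.table(path, header = TRUE, sep = sep, stringsAsFactors = FALSE)
  if ("padj" %in% names(dt) && !"fdr" %in% names(dt))
    names(dt)[names(dt) == "padj"] <- "fdr"
  need <- c("gene", "lfc", "fdr", "mean_1", "mean_2")
  miss <- setdiff(need, names(dt))
  if (length(miss))
    stop("format error: DE table missing columns: ", paste(miss, collapse = ", "))
  if (any(dt$fdr < 0 | dt$fdr > 1, na.rm = TRUE))
    stop("format error: fdr outside [0, 1]")
  attr(dt, "source") <- "external"
  class(dt) <- c("differential_table", class(dt))
  dt
}

de_mean_gate <- function(dt, mean_thr, mean_mode) {
  if (mean_mode == "any") dt$mean_1 > mean_thr | dt$mean_2 > mean_thr
  else dt$mean_1 > mean_thr & dt$mean_2 > mean_thr
}

#' Call differentially expressed genes
#'
#' `|LFC| >= lfc_thr`, `FDR <= fdr_thr` and mean expression `> mean_thr`
#' (strict, on library-normalized totals; by default required in at least
#' one phenotype). Boundary values pass the inclusive gates, matching the
#' printed operators (>= 1, <= 0.01, > 10).
#'
#' @param dt a `differential_table`.
#' @param lfc_thr,fdr_thr,mean_thr thresholds.
#' @param mean_mode `"any"` (default) or `"both"` phenotypes.
#' @return character vector of DEG gene ids.
#' @export
call_degs <- function(dt, lfc_thr = 1, fdr_thr = 0.01, mean_thr = 10,
                      mean_mode = c("any", "both")) {
  mean_mode <- match.arg(mean_mode)
  keep <- abs(dt$lfc) >= lfc_thr & dt$fdr <= fdr_thr &
    de_mean_gate(dt, mean_thr, mean_mode)
  keep[is.na(keep)] <- FALSE
  dt$gene[keep]
}

#' Call differentially angled genes
#'
#' The DAG relevance gates: full major-axis length `> axis_len_min` in
#' *both* phenotype fits (min-max-normalized coordinates; this gates the
#' reliability of both angles entering theta), `theta_window[1] < theta <
#' theta_window[2]` (strict, default 10-160 degrees), mean expression
#' `> mean_thr` and `|LFC| < lfc_max` (strict). Because DAGs require
#' `|LFC| < 1` while DEGs require `|LFC| >= 1`, the two calls never
#' overlap.
#'
#' @param stats a pair-stats data.frame (rows from [pair_stats()]).
#' @param dt a `differential_table` covering the same genes.
#' @param axis_len_min minimum full major-axis length; typically
#'   `cfg$dag_axis_len` (0.1 for the cc preset, 0.01 for crc).
#' @param theta_window open interval of acceptable theta, degrees.
#' @param mean_thr,lfc_max expression and fold-change gates.
#' @param mean_mode `"any"` (default) or `"both"`.
#' @return character vector of DAG gene ids.
#' @export
call_dags <- function(stats, dt, axis_len_min = 0.01,
                      theta_window = c(10, 160), mean_thr = 10, lfc_max = 1,
                      mean_mode = c("any", "both")) {
  mean_mode <- match.arg(mean_mode)
  idx <- match(stats$gene, dt$gene)
  if (anyNA(idx)) stop("stats and DE table must cover the same genes")
  lfc <- dt$lfc[idx]
  mg <- de_mean_gate(dt[idx, , drop = FALSE], mean_thr, mean_mode)
  keep <- stats$major_len_1 > axis_len_min & stats$major_len_2 > axis_len_min &
    stats$theta > theta_window[1L] & stats$theta < theta_window[2L] &
    mg & abs(lfc) < lfc_max
  keep[is.na(keep)] <- FALSE
  stats$gene[keep]
}

#' Genes recurrent across runs
#'
#' Strict intersection of per-run call sets (e.g. each batch plus the
#' pooled data).
#'
#' @param calls list of at least two character vectors.
#' @return character vector of genes present in every run.
#' @export
recurrent <- function(calls) {
  if (!is.list(calls) || length(calls) < 2L)
    stop("need call sets from at least 2 runs")
  Reduce(intersect, calls)
}

#' Rank genes by minimal semi-axis ratio
#'
#' For each gene, the rank value is the minimum over all runs and both
#' phenotypes of the semi-axis ratio (major / minor); genes are returned in
#' descending order of rank value. The ratio proxies confidence in the
#' fitted angle: near-circular fits (ratio near 1) have unstable
#' orientations and land last.
#'
#' @param fits data.frame with columns `gene`, `run`, `phenotype`,
#'   `semi_major`, `semi_minor`.
#' @return data.frame `gene`, `rank_value`, sorted descending.
#' @export
rank_dags <- function(fits) {
  need <- c("gene", "semi_major", "semi_minor")
  if (!all(need %in% names(fits)))
    stop("fits table needs columns ", paste(need, collapse = ", "))
  ratio <- fits$semi_major / fits$semi_minor
  rv <- tapply(ratio, fits$gene, min)
  out <- data.frame(gene = names(rv), rank_value = as.numeric(rv),
                    stringsAsFactors = FALSE)
  out[order(-out$rank_value), , drop = FALSE]
}

#' Rank-sum comparison of theta distributions
#'
#' Two-sided Wilcoxon (Mann-Whitney) test comparing the theta values of two
#' gene groups, typically DEGs against non-relevant genes (non-DEGs with
#' DAGs removed). The reported interval is the 95% Hodges-Lehmann shift
#' interval that accompanies the rank-sum test. Exact p-values are used for
#' small tie-free samples (the stats::wilcox.test default); ties switch to
#' the normal approximation with continuity correction.
#'
#' @param theta_group1,theta_group2 numeric vectors of theta values
#'   (degrees), both non-empty.
#' @param conf.level confidence level (default 0.95).
#' @return object of class `rank_sum_result`: `n_group1`, `n_group2`,
#'   `u_statistic`, `p_value`, `ci95`, `hl_estimate`.
#' @export
wilcoxon_theta <- function(theta_group1, theta_group2, conf.level = 0.95) {
  if (length(theta_group1) == 0L || length(theta_group2) == 0L)
    stop("both groups must be non-empty")
  wt <- suppressWarnings(
    stats::wilcox.test(theta_group1, theta_group2, conf.int = TRUE,
                       conf.level = conf.level)
  )
  structure(
    list(n_group1 = length(theta_group1), n_group2 = length(theta_group2),
         u_statistic = unname(wt$statistic), p_value = wt$p.value,
         ci95 = unname(wt$conf.int), hl_estimate = unname(wt$estimate)),
    class = "rank_sum_result"
  )
}

#' @export
print.rank_sum_result <- function(x, digits = 4, ...) {
  cat(sprintf("Two-sided Wilcoxon rank-sum on theta: n = (%d, %d)\n",
              x$n_group1, x$n_group2))
  cat(sprintf("U = %s, p = %s, HL shift %s deg, CI [%s, %s]\n",
              format(x$u_statistic), format(x$p_value, digits = digits),
              format(x$hl_estimate, digits = digits),
              format(x$ci95[1L], digits = digits),
              format(x$ci95[2L], digits = digits)))
  invisible(x)
}

#' Export pre-ranked gene lists for external GSEA
#'
#' Writes the two standard `.rnk` files (tab-separated `gene<TAB>metric`,
#' no header, sorted by decreasing metric): one ordered by the DGEA metric
#' `-log10(FDR + 0.001) * LFC`, one by the ellipse metric
#' `theta_pi * rank_value` where `theta_pi` is theta expressed in pi
#' radians (`theta_deg / 180`). No enrichment is computed here.
#'
#' @param stats pair-stats data.frame with `gene` and `theta`.
#' @param dt a `differential_table`.
#' @param ranks output of [rank_dags()] (gene, rank_value).
#' @param dir output directory.
#' @return named character vector of the two written paths.
#' @export
gsea_rank_export <- function(stats, dt, ranks, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  de_metric <- -log10(dt$fdr + 0.001) * dt$lfc
  de <- data.frame(gene = dt$gene, metric = de_metric)
  de <- de[is.finite(de$metric), ]
  de <- de[order(-de$metric), ]

  idx <- match(stats$gene, ranks$gene)
  dag_metric <- (stats$theta / 180) * ranks$rank_value[idx]
  dag <- data.frame(gene = stats$gene, metric = dag_metric)
  dag <- dag[is.finite(dag$metric), ]
  dag <- dag[order(-dag$metric), ]

  paths <- c(de = file.path(dir, "de_ranked.rnk"),
             dag = file.path(dir, "dag_ranked.rnk"))
  utils::write.table(de, paths[["de"]], sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  utils::write.table(dag, paths[["dag"]], sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(paths)
}
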