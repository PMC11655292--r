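#' Preprocessing configuration
#'
#' Bundles every threshold of the preprocessing chain. Two named presets
#' ship with the package, mirroring the settings used for the two reference
#' dataset types:
#'
#' * `"cc"` (cell-cycle-like): library-size bounds 40000-150000, a
#'   minimum of 20 non-zero cells per phenotype per gene, DAG
#'   major-axis-length gate 0.1.
#' * `"crc"` (tumor-organoid-like): library-size bounds 2000-50000, gene
#'   variance filter at 3, DAG major-axis-length gate 0.01.
#'
#' Printed bounds are treated as inclusive (`>=` min, `<=` max); the
#' mean-count gate `> 5` and the expression gate `> 10` are strict, matching
#' their printed operators.
#'
#' @param preset `"cc"`, `"crc"` or `"custom"`.
#' @param min_lib,max_lib inclusive per-cell total-count bounds.
#' @param min_gene_variance minimum sample variance of per-gene totals, or
#'   `NULL` to skip the filter.
#' @param min_mean_count per-phenotype mean-count gate (strict `>`).
#' @param min_nonzero_cells minimum non-zero cells per phenotype per gene,
#'   or `NULL` to skip.
#' @param outlier_percentile joint-outlier trim percentile (default 99).
#' @param outlier_rule `"and"` (a cell must exceed the percentile on both
#'   axes to be dropped — the default, literal reading) or `"or"`.
#' @param jitter logical; add uniform jitter of amplitude (axis range)/50
#'   after cleanup (used only for fitting; never for error evaluation or
#'   display).
#' @param seed RNG seed controlling the jitter.
#' @param dag_axis_len minimum full major-axis length (in min-max-normalized
#'   coordinates) for the DAG relevance gate.
#' @return list of class `preprocess_config`.
#' @export
preprocess_config <- function(preset = c("custom", "cc", "crc"),
                              min_lib = NULL, max_lib = NULL,
                              min_gene_variance = NULL,
                              min_mean_count = 5,
                              min_nonzero_cells = NULL,
                              outlier_percentile = 99,
                              outlier_rule = c("and", "or"),
                              jitter = TRUE, seed = 1L,
                              dag_axis_len = NULL) {
  preset <- match.arg(preset)
  outlier_rule <- match.arg(outlier_rule)
  defaults <- switch(preset,
    cc  = list(min_lib = 40000, max_lib = 150000, min_gene_variance = NULL,
               min_nonzero_cells = 20L, dag_axis_len = 0.1),
    crc = list(min_lib = 2000, max_lib = 50000, min_gene_variance = 3,
               min_nonzero_cells = NULL, dag_axis_len = 0.01),
    custom = list(min_lib = 0, max_lib = Inf, min_gene_variance = NULL,
                  min_nonzero_cells = NULL, dag_axis_len = 0.01)
  )
  cfg <- list(
    preset = preset,
    min_lib = min_lib %||% defaults$min_lib,
    max_lib = max_lib %||% defaults$max_lib,
    min_gene_variance = min_gene_variance %||% defaults$min_gene_variance,
    min_mean_count = min_mean_count,
    min_nonzero_cells = min_nonzero_cells %||% defaults$min_nonzero_cells,
    outlier_percentile = outlier_percentile,
    outlier_rule = outlier_rule,
    jitter = isTRUE(jitter),
    seed = as.integer(seed),
    dag_axis_len = dag_axis_len %||% defaults$dag_axis_len
  )
  if (cfg$min_lib >= cfg$max_lib) stop("min_lib must be < max_lib")
  if (cfg$outlier_percentile <= 0 || cfg$outlier_percentile > 100)
    stop("outlier_percentile must be in (0, 100]")
  structure(cfg, class = "preprocess_config")
}

#' @export
print.preprocess_config <- function(x, ...) {
  cat(sprintf("preprocess_config (preset %s)\n", x$preset))
  cat(sprintf("  library size: [%s, %s]\n", format(x$min_lib), format(x$max_lib)))
  cat(sprintf("  gene variance >= %s; mean count > %s; non-zero cells >= %s\n",
              x$min_gene_variance %||% "-", x$min_mean_count,
              x$min_nonzero_cells %||% "-"))
  cat(sprintf("  outlier percentile %s (%s); jitter %s; DAG axis gate %s\n",
              x$outlier_percentile, x$outlier_rule, x$jitter, x$dag_axis_len))
  invisible(x)
}

#' Filter cells by library size
#'
#' Retains cells whose total count (nascent + mature summed over genes) lies
#' within the inclusive bounds `[min_lib, max_lib]`. The gene set is
#' unchanged.
#'
#' @param m a `bimodal_matrix`.
#' @param cfg a [preprocess_config()].
#' @export
filter_cells_by_library <- function(m, cfg) {
  totals <- cell_totals(m)
  keep <- totals >= cfg$min_lib & totals <= cfg$max_lib
  if (!any(keep))
    stop("empty result: all ", length(keep), " cells outside library-size bounds")
  subset_cells(m, keep)
}

#' Filter genes by variance of total counts
#'
#' Sample variance (n-1 denominator) of each gene's per-cell totals across
#' retained cells; genes with variance >= `min_var` are kept. May return an
#' empty gene set (with a warning).
#'
#' @param m a `bimodal_matrix`.
#' @param min_var variance threshold; `0` or `NULL` is the identity.
#' @export
filter_genes_by_variance <- function(m, min_var) {
  if (is.null(min_var) || min_var <= 0) return(m)
  tot <- m$nascent + m$mature
  v <- apply(tot, 1L, stats::var)
  keep <- v >= min_var
  if (!any(keep)) warning("variance filter removed every gene")
  subset_genes(m, keep)
}

#' Normalize to library size
#'
#' Divides every count by its cell's total and multiplies by the mean
#' library size of the (already filtered, viable) cells, so that every
#' cell's new total equals the mean library size.
#'
#' @param m a `bimodal_matrix` that has passed cell filtering.
#' @export
library_normalize <- function(m) {
  totals <- cell_totals(m)
  if (any(totals == 0))
    stop("zero-total cell encountered; run filter_cells_by_library first")
  f <- mean(totals) / totals
  bimodal_matrix(sweep(m$nascent, 2L, f, `*`), sweep(m$mature, 2L, f, `*`),
                 phenotype = m$phenotype, batch = m$batch,
                 gene_ids = m$gene_ids, cell_ids = m$cell_ids)
}

#' Genes eligible for ellipse fitting
#'
#' A gene qualifies when its mean total count is strictly greater than
#' `cfg$min_mean_count` in both phenotypes, and (when
#' `cfg$min_nonzero_cells` is set) it has at least that many cells with a
#' non-zero total in both phenotypes.
#'
#' @param m a `bimodal_matrix` (normally library-normalized).
#' @param cfg a [preprocess_config()].
#' @param phenotype_pair character vector of two phenotype labels.
#' @return character vector of eligible gene ids.
#' @export
prefit_gene_gate <- function(m, cfg, phenotype_pair) {
  stopifnot(length(phenotype_pair) == 2L)
  unknown <- setdiff(phenotype_pair, unique(m$phenotype))
  if (length(unknown))
    stop("unknown phenotype label: ", paste(unknown, collapse = ", "))
  tot <- m$nascent + m$mature
  ok <- rep(TRUE, nrow(tot))
  for (ph in phenotype_pair) {
    cols <- m$phenotype == ph
    sub <- tot[, cols, drop = FALSE]
    ok <- ok & rowMeans(sub) > cfg$min_mean_count
    if (!is.null(cfg$min_nonzero_cells))
      ok <- ok & rowSums(sub > 0) >= cfg$min_nonzero_cells
  }
  m$gene_ids[ok]
}

#' Build the per-gene, per-phenotype phase-plane cloud
#'
#' The gene-wise cleanup pipeline, in fixed order:
#' 1. drop cells whose nascent, mature or total count is zero for this gene;
#' 2. min-max normalize nascent and mature independently to `[0, 1]`
#'    (by the cloud's own range, or by `scale_range` when a common scale is
#'    wanted);
#' 3. drop cells exceeding the `outlier_percentile` (type-7 quantile) on
#'    *both* axes (rule `"and"`; `"or"` available);
#' 4. optionally compute a jittered copy of the points (uniform noise of
#'    amplitude range/50 per axis, seeded) for singularity-free fitting.
#'
#' @param m a `bimodal_matrix`.
#' @param gene_id single gene identifier.
#' @param phenotype single phenotype label.
#' @param cfg a [preprocess_config()].
#' @param scale_range optional list with elements `mature` and `nascent`,
#'   each `c(min, max)`, overriding the cloud's own normalization range.
#' @return object of class `gene_cloud`: `gene_id`, `phenotype`, `points`
#'   (n x 2, columns mature then nascent, un-jittered), `points_jittered`
#'   (same shape, or `NULL`), `n_raw_cells`, `n_retained`.
#' @export
build_gene_cloud <- function(m, gene_id, phenotype, cfg, scale_range = NULL) {
  gi <- match(gene_id, m$gene_ids)
  if (is.na(gi)) stop("unknown gene: ", gene_id)
  cols <- m$phenotype == phenotype
  if (!any(cols)) stop("unknown phenotype label: ", phenotype)
  nas <- m$nascent[gi, cols]
  mat <- m$mature[gi, cols]
  n_raw <- length(nas)

  keep <- nas > 0 & mat > 0               # total > 0 implied
  nas <- nas[keep]; mat <- mat[keep]
  if (length(nas) < 6L)
    stop("insufficient points for conic fit: gene ", gene_id, ", phenotype ",
         phenotype, " retained ", length(nas), " cells")

  minmax <- function(v, rng) {
    if (is.null(rng)) rng <- range(v)
    if (diff(rng) == 0) return(rep(0, length(v)))
    (v - rng[1L]) / (rng[2L] - rng[1L])
  }
  mat_n <- minmax(mat, scale_range$mature)
  nas_n <- minmax(nas, scale_range$nascent)

  p <- cfg$outlier_percentile / 100
  qx <- stats::quantile(mat_n, p, type = 7, names = FALSE)
  qy <- stats::quantile(nas_n, p, type = 7, names = FALSE)
  out <- if (cfg$outlier_rule == "and") (mat_n > qx & nas_n > qy)
         else (mat_n > qx | nas_n > qy)
  mat_n <- mat_n[!out]; nas_n <- nas_n[!out]

  pts <- cbind(mature = unname(mat_n), nascent = unname(nas_n))
  if (nrow(pts) < 6L)
    stop("insufficient points for conic fit: gene ", gene_id, ", phenotype ",
         phenotype, " retained ", nrow(pts), " cells")
  jit <- NULL
  if (cfg$jitter) {
    set.seed(cfg$seed + gi)
    amp <- c(diff(range(pts[, 1L])), diff(range(pts[, 2L]))) / 50
    amp[amp == 0] <- 1e-6
    jit <- pts + cbind(stats::runif(nrow(pts), -amp[1L], amp[1L]),
                       stats::runif(nrow(pts), -amp[2L], amp[2L]))
  }
  structure(
    list(gene_id = gene_id, phenotype = phenotype, points = pts,
         points_jittered = jit, n_raw_cells = n_raw, n_retained = nrow(pts)),
    class = "gene_cloud"
  )
}

#' @export
print.gene_cloud <- function(x, ...) {
  cat(sprintf("gene_cloud: %s / %s, %d of %d cells retained\n",
              x$gene_id, x$phenotype, x$n_retained, x$n_raw_cells))
  invisible(x)
}

#' Fit an ellipse to a gene cloud
#'
#' Fits on the jittered coordinates when present (avoiding moment-matrix
#' singularity) while evaluating the fit error on the un-jittered points.
#'
#' @param cloud a `gene_cloud`.
#' @param strategy,rmsd_method see [fit_ellipse()].
#' @return an `ellipse_fit`.
#' @export
fit_gene_cloud <- function(cloud, strategy = "free", rmsd_method = "mean_abs") {
  stopifnot(inherits(cloud, "gene_cloud"))
  pts <- cloud$points_jittered %||% cloud$points
  fit_ellipse(pts, strategy, rmsd_points = cloud$points, rmsd_method = rmsd_method)
}

#' KNN smoothing of cell profiles (demonstration only)
#'
#' Replaces each cell's joint (nascent, mature) profile by the mean over its
#' `k` nearest neighbours (Euclidean distance on the concatenated per-cell
#' vectors of all genes; the cell itself counts among its neighbours, so
#' `k = 1` is the identity). With `mode = "separate"` the neighbour search
#' is restricted to the cell's own phenotype.
#'
#' Smoothing is provided to demonstrate how it distorts phase-plane shape
#' information; it is not part of the recommended pipeline.
#'
#' @param m a `bimodal_matrix`.
#' @param k number of neighbours (>= 1, including self).
#' @param mode `"separate"` or `"together"`.
#' @export
knn_smooth <- function(m, k, mode = c("separate", "together")) {
  mode <- match.arg(mode)
  if (k < 1) stop("k must be >= 1")
  X <- rbind(m$nascent, m$mature)          # 2G x C
  nas <- m$nascent; mat <- m$mature
  pools <- if (mode == "together") list(seq_len(ncol(X)))
           else split(seq_len(ncol(X)), m$phenotype)
  for (pool in pools) {
    if (k > length(pool))
      stop("k = ", k, " exceeds pool size ", length(pool))
    D <- as.matrix(stats::dist(t(X[, pool, drop = FALSE])))
    for (j in seq_along(pool)) {
      nn <- pool[order(D[j, ])[seq_len(k)]]
      nas[, pool[j]] <- rowMeans(m$nascent[, nn, drop = FALSE])
      mat[, pool[j]] <- rowMeans(m$mature[, nn, drop = FALSE])
    }
  }
  bimodal_matrix(nas, mat, phenotype = m$phenotype, batch = m$batch,
                 gene_ids = m$gene_ids, cell_ids = m$cell_ids)
}

#' Run the full preprocessing chain
#'
#' Cell-level filtering, optional gene variance filter and library
#' normalization, in the fixed published order. Returns the normalized
#' matrix plus a record of per-stage counts for the run manifest.
#'
#' @param m a `bimodal_matrix`.
#' @param cfg a [preprocess_config()].
#' @return list with `matrix` (the processed `bimodal_matrix`) and `counts`
#'   (named list of cells/genes after each stage).
#' @export
preprocess <- function(m, cfg) {
  counts <- list(input_cells = ncol(m$nascent), input_genes = nrow(m$nascent))
  m <- filter_cells_by_library(m, cfg)
  counts$cells_after_library_filter <- ncol(m$nascent)
  m <- filter_genes_by_variance(m, cfg$min_gene_variance)
  counts$genes_after_variance_filter <- nrow(m$nascent)
  m <- library_normalize(m)
  list(matrix = m, counts = counts)
}
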