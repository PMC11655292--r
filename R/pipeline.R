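#' Per-gene phase-plane clouds for a phenotype pair on a shared scale
#'
#' Builds the two phenotype clouds of one gene with min-max normalization
#' on the shared per-gene range of the pooled pair (zero cells excluded),
#' so that the two fitted ellipses live in one coordinate system and their
#' overlap is meaningful. Outlier trimming and jitter still happen per
#' phenotype, as in [build_gene_cloud()].
#'
#' @param m a `bimodal_matrix`.
#' @param gene_id gene identifier.
#' @param phenotype_pair two phenotype labels.
#' @param cfg a [preprocess_config()].
#' @return list of two `gene_cloud` objects (named by phenotype).
#' @export
gene_pair_clouds <- function(m, gene_id, phenotype_pair, cfg) {
  gi <- match(gene_id, m$gene_ids)
  if (is.na(gi)) stop("unknown gene: ", gene_id)
  cols <- m$phenotype %in% phenotype_pair
  nas <- m$nascent[gi, cols]; mat <- m$mature[gi, cols]
  keep <- nas > 0 & mat > 0
  if (!any(keep)) stop("gene ", gene_id, " has no non-zero cells in the pair")
  rng <- list(mature = range(mat[keep]), nascent = range(nas[keep]))
  out <- lapply(phenotype_pair, function(ph)
    build_gene_cloud(m, gene_id, ph, cfg, scale_range = rng))
  names(out) <- phenotype_pair
  out
}

#' Fit both phenotypes of every eligible gene
#'
#' Applies the pre-fit gene gate, builds shared-scale clouds and fits the
#' chosen strategy per phenotype. Genes whose cleanup leaves too few points
#' are skipped (recorded in the `skipped` attribute).
#'
#' @param m a preprocessed (library-normalized) `bimodal_matrix`.
#' @param cfg a [preprocess_config()].
#' @param phenotype_pair two phenotype labels.
#' @param strategy fitting strategy, see [fit_ellipse()].
#' @param run_id label recorded in the output table.
#' @return list with `fits` (nested list gene -> phenotype -> `ellipse_fit`)
#'   and `table` (one row per gene x phenotype: gene, run, phenotype,
#'   conic a..f, center, semi-axes, phi, rmsd, n_points, strategy).
#' @export
fit_all_genes <- function(m, cfg, phenotype_pair, strategy = "free",
                          run_id = "run1") {
  genes <- prefit_gene_gate(m, cfg, phenotype_pair)
  fits <- list()
  rows <- list()
  skipped <- character(0)
  for (g in genes) {
    res <- tryCatch({
      clouds <- gene_pair_clouds(m, g, phenotype_pair, cfg)
      lapply(clouds, fit_gene_cloud, strategy = strategy)
    }, error = function(e) NULL)
    if (is.null(res)) { skipped <- c(skipped, g); next }
    fits[[g]] <- res
    for (ph in phenotype_pair) {
      f <- res[[ph]]
      rows[[length(rows) + 1L]] <- data.frame(
        gene = g, run = run_id, phenotype = ph,
        a = f$conic[["a"]], b = f$conic[["b"]], c = f$conic[["c"]],
        d = f$conic[["d"]], e = f$conic[["e"]], f = f$conic[["f"]],
        x0 = f$geometry$center[1L], y0 = f$geometry$center[2L],
        semi_major = f$geometry$semi_major, semi_minor = f$geometry$semi_minor,
        phi = f$geometry$phi, rmsd = f$rmsd, n_points = f$n_points,
        strategy = f$strategy, stringsAsFactors = FALSE
      )
    }
  }
  tab <- if (length(rows)) do.call(rbind, rows) else NULL
  structure(list(fits = fits, table = tab), skipped = skipped)
}

#' Pair statistics for all fitted genes
#'
#' @param fits output of [fit_all_genes()].
#' @param phenotype_pair the two phenotype labels (order fixes which fit is
#'   1 and 2; theta and omega are symmetric).
#' @param resolution,theta_thr,omega_thr see [pair_stats()].
#' @return data.frame, one row per gene.
#' @export
stats_all_genes <- function(fits, phenotype_pair, resolution = 512L,
                            theta_thr = 10, omega_thr = 0.5) {
  rows <- lapply(names(fits$fits), function(g) {
    fl <- fits$fits[[g]]
    pair_stats(fl[[phenotype_pair[1L]]], fl[[phenotype_pair[2L]]], g,
               resolution, theta_thr, omega_thr)
  })
  do.call(rbind, rows)
}

#' Run the full modality-discovery pipeline
#'
#' One call from a raw `bimodal_matrix` to recurrent DEG/DAG calls: for
#' each batch and for the pooled data (the "runs"), preprocess, fit both
#' phenotypes of every eligible gene, compute pair statistics, call DEGs
#' and DAGs, then intersect calls across runs and rank genes by minimal
#' semi-axis ratio.
#'
#' @param m a raw `bimodal_matrix` with at least the two phenotypes.
#' @param cfg a [preprocess_config()].
#' @param phenotype_pair two phenotype labels.
#' @param de_tables optional named list of externally produced
#'   `differential_table`s, one per run; the built-in rank-sum fallback is
#'   used for runs without one.
#' @param resolution omega grid resolution (default 512).
#' @param strategy fitting strategy.
#' @param include_pooled include the pooled-data run (default TRUE when
#'   more than one batch).
#' @return object of class `dagfit_result`: per-run `fits`, `stats`, `de`,
#'   `degs`, `dags`, plus `recurrent_degs`, `recurrent_dags`, `ranks` and
#'   the `manifest` of per-stage counts.
#' @export
run_pipeline <- function(m, cfg, phenotype_pair, de_tables = NULL,
                         resolution = 512L, strategy = "free",
                         include_pooled = NULL) {
  stopifnot(inherits(m, "bimodal_matrix"))
  batches <- unique(m$batch)
  if (is.null(include_pooled)) include_pooled <- length(batches) > 1L
  runs <- as.list(batches)
  names(runs) <- batches
  if (include_pooled) runs$pooled <- batches

  per_run <- list()
  manifest <- list()
  for (rn in names(runs)) {
    sub <- subset_cells(m, m$batch %in% runs[[rn]])
    prep <- preprocess(sub, cfg)
    fits <- fit_all_genes(prep$matrix, cfg, phenotype_pair, strategy, rn)
    if (is.null(fits$table)) stop("no genes could be fitted in run ", rn)
    st <- stats_all_genes(fits, phenotype_pair, resolution)
    de <- de_tables[[rn]] %||% compute_builtin_de(prep$matrix, phenotype_pair)
    de <- de[de$gene %in% st$gene, , drop = FALSE]
    degs <- call_degs(de)
    dags <- call_dags(st, de, axis_len_min = cfg$dag_axis_len)
    per_run[[rn]] <- list(fits = fits, stats = st, de = de,
                          degs = degs, dags = dags)
    manifest[[rn]] <- c(prep$counts,
                        list(genes_fitted = length(fits$fits),
                             degs = length(degs), dags = length(dags)))
  }
  all_fit_tables <- do.call(rbind, lapply(per_run, function(r) r$fits$table))
  structure(
    list(runs = per_run,
         recurrent_degs = recurrent(lapply(per_run, function(r) r$degs)),
         recurrent_dags = recurrent(lapply(per_run, function(r) r$dags)),
         ranks = rank_dags(all_fit_tables),
         phenotype_pair = phenotype_pair, config = cfg,
         manifest = manifest),
    class = "dagfit_result"
  )
}

#' @export
print.dagfit_result <- function(x, ...) {
  cat(sprintf("dagfit pipeline result: %d runs (%s)\n",
              length(x$runs), paste(names(x$runs), collapse = ", ")))
  for (rn in names(x$runs))
    cat(sprintf("  %-8s %4d genes fitted, %3d DEGs, %3d DAGs\n", rn,
                length(x$runs[[rn]]$fits$fits),
                length(x$runs[[rn]]$degs), length(x$runs[[rn]]$dags)))
  cat(sprintf("recurrent: %d DEGs, %d DAGs (DEG/DAG overlap: %d)\n",
              length(x$recurrent_degs), length(x$recurrent_dags),
              length(intersect(x$recurrent_degs, x$recurrent_dags))))
  invisible(x)
}

#' Write a run manifest
#'
#' JSON record of a pipeline invocation: configuration snapshot, input
#' paths, seed, package version, per-stage record counts, timestamp.
#'
#' @param dir output directory.
#' @param config a [preprocess_config()] (or any list).
#' @param counts per-stage record counts.
#' @param seed the seed used.
#' @param inputs character vector of input paths.
#' @return the manifest path, invisibly.
#' @export
write_manifest <- function(dir, config, counts, seed = NA, inputs = character(0)) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(
    tool = "dagfit",
    version = as.character(utils::packageVersion("dagfit")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    seed = seed, inputs = inputs,
    config = unclass(config), counts = counts
  )
  path <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE,
                       null = "null")
  invisible(path)
}

#' Phase plot of one gene with ellipse overlays
#'
#' Scatter of the two phenotype clouds (un-jittered points, as fits are
#' displayed) with the fitted ellipses drawn as solid lines.
#'
#' @param clouds list of two `gene_cloud`s (from [gene_pair_clouds()]).
#' @param fits list of two `ellipse_fit`s matching `clouds`.
#' @param cols two colors.
#' @param main plot title (default: the gene id).
#' @export
plot_gene_phase <- function(clouds, fits, cols = c("#2166ac", "#b2182b"),
                            main = NULL) {
  stopifnot(length(clouds) == 2L, length(fits) == 2L)
  pts <- rbind(clouds[[1L]]$points, clouds[[2L]]$points)
  per <- rbind(predict(fits[[1L]]), predict(fits[[2L]]))
  graphics::plot(NA, xlim = range(c(pts[, 1L], per[, 1L])),
                 ylim = range(c(pts[, 2L], per[, 2L])),
                 xlab = "mature", ylab = "nascent",
                 main = main %||% clouds[[1L]]$gene_id)
  for (i in 1:2) {
    graphics::points(clouds[[i]]$points, pch = 16, cex = 0.5, col = cols[i])
    p <- predict(fits[[i]])
    graphics::lines(rbind(p, p[1L, , drop = FALSE]), col = cols[i], lwd = 2)
  }
  graphics::legend("topleft", legend = vapply(clouds, `[[`, "", "phenotype"),
                   col = cols, pch = 16, bty = "n")
  invisible(NULL)
}
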