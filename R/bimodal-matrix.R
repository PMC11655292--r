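#' Construct a bimodal (two-layer) count matrix
#'
#' The pipeline substrate: genes x cells counts measured in two layers —
#' nascent (unspliced / newly synthesized) and mature (spliced /
#' pre-existing) — together with one phenotype and one batch label per cell.
#'
#' @param nascent,mature genes x cells numeric matrices of identical shape
#'   and index order; all values must be non-negative.
#' @param phenotype character/factor of length `ncol`, one label per cell.
#' @param batch optional batch label per cell (default: single batch "b1").
#' @param gene_ids,cell_ids identifiers; default taken from dimnames or
#'   generated.
#' @return object of class `bimodal_matrix`.
#' @export
bimodal_matrix <- function(nascent, mature, phenotype, batch = NULL,
                           gene_ids = NULL, cell_ids = NULL) {
  nascent <- as.matrix(nascent); mature <- as.matrix(mature)
  if (!identical(dim(nascent), dim(mature)))
    stop("format error: nascent and mature layers have different shapes (",
         paste(dim(nascent), collapse = "x"), " vs ",
         paste(dim(mature), collapse = "x"), ")")
  if (any(nascent < 0) || any(mature < 0))
    stop("format error: negative counts")
  ng <- nrow(nascent); nc <- ncol(nascent)
  if (is.null(gene_ids)) gene_ids <- rownames(nascent) %||% paste0("gene", seq_len(ng))
  if (is.null(cell_ids)) cell_ids <- colnames(nascent) %||% paste0("cell", seq_len(nc))
  if (length(gene_ids) != ng || length(cell_ids) != nc)
    stop("format error: identifier lengths do not match matrix shape")
  if (missing(phenotype) || is.null(phenotype))
    stop("format error: missing phenotype labels")
  phenotype <- as.character(phenotype)
  if (length(phenotype) != nc || anyNA(phenotype))
    stop("format error: phenotype must provide one label per cell")
  if (is.null(batch)) batch <- rep("b1", nc)
  batch <- as.character(batch)
  if (length(batch) != nc || anyNA(batch))
    stop("format error: batch must provide one label per cell")
  dimnames(nascent) <- dimnames(mature) <- list(gene_ids, cell_ids)
  structure(
    list(nascent = nascent, mature = mature,
         gene_ids = gene_ids, cell_ids = cell_ids,
         phenotype = phenotype, batch = batch),
    class = "bimodal_matrix"
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
dim.bimodal_matrix <- function(x) dim(x$nascent)

#' @export
print.bimodal_matrix <- function(x, ...) {
  cat(sprintf("bimodal_matrix: %d genes x %d cells\n", nrow(x$nascent), ncol(x$nascent)))
  cat("phenotypes:", paste(sprintf("%s (%d)", names(table(x$phenotype)),
                                   table(x$phenotype)), collapse = ", "), "\n")
  cat("batches:   ", paste(names(table(x$batch)), collapse = ", "), "\n")
  invisible(x)
}

#' Per-cell total counts (nascent + mature summed over genes)
#' @param m a `bimodal_matrix`.
#' @return numeric vector, one total per cell.
#' @export
cell_totals <- function(m) {
  stopifnot(inherits(m, "bimodal_matrix"))
  colSums(m$nascent) + colSums(m$mature)
}

subset_cells <- function(m, keep) {
  bimodal_matrix(m$nascent[, keep, drop = FALSE], m$mature[, keep, drop = FALSE],
                 phenotype = m$phenotype[keep], batch = m$batch[keep],
                 gene_ids = m$gene_ids, cell_ids = m$cell_ids[keep])
}

subset_genes <- function(m, keep) {
  bimodal_matrix(m$nascent[keep, , drop = FALSE], m$mature[keep, , drop = FALSE],
                 phenotype = m$phenotype, batch = m$batch,
                 gene_ids = m$gene_ids[keep], cell_ids = m$cell_ids)
}

#' Read a bimodal matrix from disk
#'
#' Two layouts are supported:
#'
#' * `layout = "mtx"`: one Matrix Market file per layer plus delimited
#'   sidecars. `paths` must name `nascent`, `mature`, `features` (one gene
#'   id per line), `barcodes` (one cell id per line) and `labels` (TSV with
#'   header `cell_id, phenotype, batch`).
#' * `layout = "long"`: a single delimited table with header
#'   `gene, cell, nascent, mature`, plus the same `labels` sidecar given as
#'   `paths["labels"]`. Missing (gene, cell) pairs are zeros.
#'
#' @param paths named character vector or list of file paths (see layouts).
#' @param layout `"mtx"` or `"long"`.
#' @param sep field separator of delimited files (default tab).
#' @return a validated [bimodal_matrix()].
#' @export
read_bimodal <- function(paths, layout = c("mtx", "long"), sep = "\t") {
  layout <- match.arg(layout)
  paths <- as.list(paths)
  need <- if (layout == "mtx") c("nascent", "mature", "features", "barcodes", "labels")
          else c("table", "labels")
  miss <- setdiff(need, names(paths))
  if (length(miss))
    stop("format error: missing paths: ", paste(miss, collapse = ", "))
  for (p in unlist(paths[need]))
    if (!file.exists(p)) stop("format error: file not found: ", p)

  labels <- utils::read.table(paths$labels, header = TRUE, sep = sep,
                              stringsAsFactors = FALSE)
  if (!all(c("cell_id", "phenotype", "batch") %in% names(labels)))
    stop("format error: labels file needs columns cell_id, phenotype, batch")

  if (layout == "mtx") {
    nas <- as.matrix(Matrix::readMM(paths$nascent))
    mat <- as.matrix(Matrix::readMM(paths$mature))
    genes <- readLines(paths$features)
    cells <- readLines(paths$barcodes)
    if (nrow(nas) != length(genes) || ncol(nas) != length(cells))
      stop("format error: sidecar lengths do not match matrix shape")
  } else {
    tab <- utils::read.table(paths$table, header = TRUE, sep = sep,
                             stringsAsFactors = FALSE)
    if (!all(c("gene", "cell", "nascent", "mature") %in% names(tab)))
      stop("format error: long table needs columns gene, cell, nascent, mature")
    genes <- unique(tab$gene)
    cells <- unique(tab$cell)
    gi <- match(tab$gene, genes); ci <- match(tab$cell, cells)
    nas <- mat <- matrix(0, length(genes), length(cells))
    nas[cbind(gi, ci)] <- tab$nascent
    mat[cbind(gi, ci)] <- tab$mature
  }
  idx <- match(cells, labels$cell_id)
  if (anyNA(idx)) stop("format error: labels missing for some cells")
  bimodal_matrix(nas, mat, phenotype = labels$phenotype[idx],
                 batch = labels$batch[idx], gene_ids = genes, cell_ids = cells)
}

#' Write a bimodal matrix to disk
#'
#' Writes the MTX + sidecar encoding (`layout = "mtx"`) or the long
#' delimited table (`layout = "long"`); both are re-readable with
#' [read_bimodal()]. Returns the named path set invisibly.
#'
#' @param m a `bimodal_matrix`.
#' @param dir output directory (created if needed).
#' @param layout `"mtx"` or `"long"`.
#' @param sep field separator.
#' @export
write_bimodal <- function(m, dir, layout = c("mtx", "long"), sep = "\t") {
  layout <- match.arg(layout)
  stopifnot(inherits(m, "bimodal_matrix"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  labels <- data.frame(cell_id = m$cell_ids, phenotype = m$phenotype,
                       batch = m$batch)
  lab_path <- file.path(dir, "labels.tsv")
  utils::write.table(labels, lab_path, sep = sep, quote = FALSE, row.names = FALSE)
  if (layout == "mtx") {
    paths <- list(nascent = file.path(dir, "nascent.mtx"),
                  mature = file.path(dir, "mature.mtx"),
                  features = file.path(dir, "features.tsv"),
                  barcodes = file.path(dir, "barcodes.tsv"),
                  labels = lab_path)
    Matrix::writeMM(Matrix::Matrix(m$nascent, sparse = TRUE), paths$nascent)
    Matrix::writeMM(Matrix::Matrix(m$mature, sparse = TRUE), paths$mature)
    writeLines(m$gene_ids, paths$features)
    writeLines(m$cell_ids, paths$barcodes)
  } else {
    tab <- data.frame(
      gene = rep(m$gene_ids, times = ncol(m$nascent)),
      cell = rep(m$cell_ids, each = nrow(m$nascent)),
      nascent = as.vector(m$nascent),
      mature = as.vector(m$mature)
    )
    paths <- list(table = file.path(dir, "bimodal_long.tsv"), labels = lab_path)
    utils::write.table(tab, paths$table, sep = sep, quote = FALSE, row.names = FALSE)
  }
  invisible(paths)
}
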