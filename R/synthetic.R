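#' Scenario presets for the synthetic-data generator
#'
#' Each preset describes, per phenotype, a bivariate normal cloud in the
#' (mature, nascent) phase plane: center, 2-sigma semi-axes `(A, B)`,
#' major-axis orientation `phi` (degrees), a count scale, and a dropout
#' rate (fraction of cells in which the gene is not captured at all). The
#' four scenarios realize the 2x2 modality scheme (small/large overlap x
#' small/large angle difference), plus a `"non_relevant"` preset with
#' identical distributions in both phenotypes:
#'
#' * scenario 1 — disjoint clouds, equal angles, 3.7x total-count shift:
#'   a classic DEG with near-zero overlap.
#' * scenario 2 — separated thin clouds crossed at 90 degrees, equal total
#'   expression: a DAG with small overlap.
#' * scenario 3 — nested same-angle ellipses, expression shift realized
#'   through expression frequency (dropout 0.65 vs 0.05; the gene fires in
#'   far fewer cells of phenotype 1 but with identical kinetics when on):
#'   a DEG with large overlap (analytic Dice about 0.62).
#' * scenario 4 — co-centered clouds crossed at 45 degrees, equal
#'   expression: a DAG with large overlap (about 0.8).
#'
#' The numbers are package conventions chosen so each preset's analytic
#' theta and overlap fall inside its scenario's quadrant with a margin, and
#' so all clouds stay essentially positive at the default count scale.
#'
#' @param scenario `1:4` or `"non_relevant"`.
#' @param n_cells cells per phenotype (default 300).
#' @param count_scale multiplicative map from the unit phase plane to
#'   counts (default 40).
#' @param dropout_rate length-2 dropout per phenotype, or a single rate for
#'   both; overrides the preset's own default when given.
#' @param swap_phenotypes logical; exchange the two phenotype roles (used
#'   to balance fold-change directions in simulated datasets).
#' @return list of class `scenario_preset`.
#' @export
scenario_preset <- function(scenario, n_cells = 300L, count_scale = 40,
                            dropout_rate = NULL, swap_phenotypes = FALSE) {
  key <- as.character(scenario)
  p <- switch(key,
    "1" = list(center_1 = c(0.35, 0.35), center_2 = c(1.30, 1.30),
               axes_1 = c(0.30, 0.15), axes_2 = c(0.30, 0.15),
               phi_1 = 45, phi_2 = 45, dropout = c(0.05, 0.05),
               expected_call = "DEG"),
    "2" = list(center_1 = c(0.38, 0.72), center_2 = c(0.72, 0.38),
               axes_1 = c(0.32, 0.10), axes_2 = c(0.32, 0.10),
               phi_1 = 68, phi_2 = 158, dropout = c(0.05, 0.05),
               expected_call = "DAG"),
    "3" = list(center_1 = c(0.55, 0.55), center_2 = c(0.55, 0.55),
               axes_1 = c(0.45, 0.17), axes_2 = c(0.62, 0.26),
               phi_1 = 45, phi_2 = 45, dropout = c(0.65, 0.05),
               expected_call = "DEG"),
    "4" = list(center_1 = c(0.60, 0.60), center_2 = c(0.60, 0.60),
               axes_1 = c(0.40, 0.25), axes_2 = c(0.40, 0.25),
               phi_1 = 67.5, phi_2 = 112.5, dropout = c(0.05, 0.05),
               expected_call = "DAG"),
    "non_relevant" = list(center_1 = c(0.55, 0.55), center_2 = c(0.55, 0.55),
                          axes_1 = c(0.36, 0.18), axes_2 = c(0.36, 0.18),
                          phi_1 = 45, phi_2 = 45, dropout = c(0.05, 0.05),
                          expected_call = "non_relevant"),
    stop("unknown scenario: ", scenario)
  )
  if (!is.null(dropout_rate)) p$dropout <- rep(dropout_rate, length.out = 2L)
  if (any(p$dropout < 0 | p$dropout >= 1)) stop("dropout_rate must be in [0, 1)")
  if (swap_phenotypes) {
    p[c("center_1", "center_2")] <- p[c("center_2", "center_1")]
    p[c("axes_1", "axes_2")] <- p[c("axes_2", "axes_1")]
    p[c("phi_1", "phi_2")] <- p[c("phi_2", "phi_1")]
    p$dropout <- rev(p$dropout)
  }
  p$scenario <- if (key == "non_relevant") NA_integer_ else as.integer(key)
  p$n_cells <- as.integer(n_cells)
  p$count_scale <- count_scale
  structure(p, class = "scenario_preset")
}

# sample one phenotype cloud: bivariate normal -> scale -> round -> clamp at 0,
# then whole-cell dropout zeros
sample_cloud <- function(n, center, axes, phi, count_scale, dropout) {
  t <- phi * pi / 180
  u <- stats::rnorm(n, sd = axes[1L] / 2)
  v <- stats::rnorm(n, sd = axes[2L] / 2)
  x <- center[1L] + u * cos(t) - v * sin(t)
  y <- center[2L] + u * sin(t) + v * cos(t)
  cnt <- cbind(mature = pmax(0, round(x * count_scale)),
               nascent = pmax(0, round(y * count_scale)))
  off <- stats::runif(n) < dropout
  cnt[off, ] <- 0
  cnt
}

#' Simulate one gene under a scenario preset
#'
#' Draws the two phenotype clouds (integer counts, dropout zeros included)
#' and the attached ground truth.
#'
#' @param preset a [scenario_preset()].
#' @param seed integer seed.
#' @return list with `cloud_1`, `cloud_2` (n x 2 integer count matrices,
#'   columns mature, nascent) and `truth` (scenario, true phis, true theta,
#'   expected call).
#' @export
simulate_gene <- function(preset, seed = 1L) {
  stopifnot(inherits(preset, "scenario_preset"))
  if (preset$n_cells < 20L)
    warning("fewer than 20 cells per phenotype: ellipse fits will be unreliable")
  set.seed(as.integer(seed))
  c1 <- sample_cloud(preset$n_cells, preset$center_1, preset$axes_1,
                     preset$phi_1, preset$count_scale, preset$dropout[1L])
  c2 <- sample_cloud(preset$n_cells, preset$center_2, preset$axes_2,
                     preset$phi_2, preset$count_scale, preset$dropout[2L])
  th <- abs(preset$phi_1 %% 180 - preset$phi_2 %% 180)
  list(cloud_1 = c1, cloud_2 = c2,
       truth = list(scenario = preset$scenario,
                    true_phi_1 = preset$phi_1 %% 180,
                    true_phi_2 = preset$phi_2 %% 180,
                    true_theta = th,
                    expected_call = preset$expected_call))
}

#' Fit and classify a simulated (or any) phenotype pair of point clouds
#'
#' Convenience route from two raw count clouds to the pair statistics:
#' drops cells with a zero on either axis, fits the free ellipse to each
#' cloud and returns the [pair_stats()] row.
#'
#' @param cloud_1,cloud_2 n x 2 matrices (mature, nascent).
#' @param gene_id identifier for the output row.
#' @param resolution,theta_thr,omega_thr see [pair_stats()].
#' @export
classify_gene_pair <- function(cloud_1, cloud_2, gene_id = NA_character_,
                               resolution = 512L, theta_thr = 10,
                               omega_thr = 0.5) {
  clean <- function(p) p[p[, 1L] > 0 & p[, 2L] > 0, , drop = FALSE]
  f1 <- fit_ellipse(clean(cloud_1))
  f2 <- fit_ellipse(clean(cloud_2))
  pair_stats(f1, f2, gene_id, resolution, theta_thr, omega_thr)
}

#' Simulate a multi-batch bimodal dataset with known modality structure
#'
#' Genes from all four scenario presets plus non-relevant fillers, over
#' several batches with small per-batch parameter perturbations (so planted
#' recurrent genes survive the cross-run intersection). Half of the
#' scenario-1 and scenario-3 genes shift up in each phenotype, balancing
#' library composition between phenotypes. Per-cell library sizes get a
#' log-normal factor; a planted fraction of cells is pushed below (and
#' another above) the library-size bounds so the cell filters are
#' exercised.
#'
#' @param n_genes_per_scenario genes per scenario (default 20).
#' @param n_nonrelevant non-relevant filler genes (default: same).
#' @param n_batches number of batches (default 3).
#' @param n_cells cells per phenotype per batch (default 150).
#' @param count_scale see [scenario_preset()].
#' @param libsize_model list: `sdlog` of the log-normal library factor,
#'   `frac_low`/`low_total` (fraction of cells forced to about this total,
#'   below the lower bound) and `frac_high`/`high_total`.
#' @param seed integer master seed; per-gene, per-batch streams are derived
#'   from it so individual genes are reproducible.
#' @return list with `matrix` (a [bimodal_matrix()]), `truth` (per-gene
#'   data.frame: gene, scenario, expected_call, true phis/theta) and
#'   `planted_low` / `planted_high` (cell ids pushed outside the library
#'   bounds).
#' @export
simulate_dataset <- function(n_genes_per_scenario = 20L,
                             n_nonrelevant = n_genes_per_scenario,
                             n_batches = 3L, n_cells = 150L,
                             count_scale = 40,
                             libsize_model = list(sdlog = 0.15,
                                                  frac_low = 0.05,
                                                  low_total = 500,
                                                  frac_high = 0.02,
                                                  high_total = 75000),
                             seed = 1L) {
  scenarios <- c(rep(c("1", "2", "3", "4"), each = n_genes_per_scenario),
                 rep("non_relevant", n_nonrelevant))
  gene_ids <- c(
    sprintf("s%s_g%02d", rep(c("1", "2", "3", "4"), each = n_genes_per_scenario),
            rep(seq_len(n_genes_per_scenario), 4L)),
    sprintf("nr_g%02d", seq_len(n_nonrelevant))
  )
  ng <- length(gene_ids)
  cells_per_batch <- 2L * n_cells
  nc <- n_batches * cells_per_batch
  nas <- mat <- matrix(0, ng, nc)
  phenotype <- rep(rep(c("ph1", "ph2"), each = n_cells), n_batches)
  batch <- rep(sprintf("b%d", seq_len(n_batches)), each = cells_per_batch)
  cell_ids <- sprintf("%s_%s_c%03d", batch, phenotype,
                      rep(seq_len(n_cells), 2L * n_batches))

  truth <- data.frame(gene = gene_ids, scenario = NA_integer_,
                      expected_call = NA_character_,
                      true_phi_1 = NA_real_, true_phi_2 = NA_real_,
                      true_theta = NA_real_, stringsAsFactors = FALSE)

  for (g in seq_len(ng)) {
    swap <- scenarios[g] %in% c("1", "3") && (g %% 2L == 0L)
    for (b in seq_len(n_batches)) {
      preset <- scenario_preset(scenarios[g], n_cells = n_cells,
                                count_scale = count_scale,
                                swap_phenotypes = swap)
      gb_seed <- (as.double(seed) * 100003 + g * 131 + b * 7) %% 2147483647
      set.seed(as.integer(gb_seed))
      # small per-batch perturbation; kept well inside the scenario quadrant
      preset$phi_1 <- (preset$phi_1 + stats::runif(1, -3, 3)) %% 180
      preset$phi_2 <- (preset$phi_2 + stats::runif(1, -3, 3)) %% 180
      preset$center_1 <- preset$center_1 * (1 + stats::runif(2, -0.03, 0.03))
      preset$center_2 <- preset$center_2 * (1 + stats::runif(2, -0.03, 0.03))
      sim <- simulate_gene(preset, seed = as.integer((gb_seed + 17) %% 2147483647))
      cols <- which(batch == sprintf("b%d", b))
      c1 <- cols[phenotype[cols] == "ph1"]
      c2 <- cols[phenotype[cols] == "ph2"]
      mat[g, c1] <- sim$cloud_1[, "mature"]; nas[g, c1] <- sim$cloud_1[, "nascent"]
      mat[g, c2] <- sim$cloud_2[, "mature"]; nas[g, c2] <- sim$cloud_2[, "nascent"]
      if (b == 1L) {
        tr <- sim$truth
        truth$scenario[g] <- tr$scenario %||% NA_integer_
        truth$expected_call[g] <- tr$expected_call
        truth$true_phi_1[g] <- tr$true_phi_1
        truth$true_phi_2[g] <- tr$true_phi_2
        truth$true_theta[g] <- tr$true_theta
      }
    }
  }

  # library-size variation and planted out-of-bounds cells
  set.seed(as.integer((as.double(seed) * 7919 + 13) %% 2147483647))
  f <- stats::rlnorm(nc, 0, libsize_model$sdlog)
  totals <- colSums(nas) + colSums(mat)
  n_low <- round(libsize_model$frac_low * nc)
  n_high <- round(libsize_model$frac_high * nc)
  planted <- sample.int(nc, n_low + n_high)
  low <- planted[seq_len(n_low)]
  high <- planted[n_low + seq_len(n_high)]
  f[low] <- libsize_model$low_total / totals[low]
  f[high] <- libsize_model$high_total / totals[high]
  nas <- round(sweep(nas, 2L, f, `*`))
  mat <- round(sweep(mat, 2L, f, `*`))

  m <- bimodal_matrix(nas, mat, phenotype = phenotype, batch = batch,
                      gene_ids = gene_ids, cell_ids = cell_ids)
  list(matrix = m, truth = truth,
       planted_low = cell_ids[low], planted_high = cell_ids[high])
}
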