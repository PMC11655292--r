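#' Angle difference between two phenotype fits
#'
#' `theta = |phi_1 - phi_2|`, the raw absolute difference of the two
#' major-axis orientations in degrees. It is deliberately *not* folded to
#' `[0, 90]`: the DAG relevance window `theta > 10 and theta < 160`
#' presupposes the raw difference, so a pair like (5, 175) yields 170 and
#' is excluded by the window even though the axes are geometrically close.
#'
#' @param phi_1,phi_2 major-axis orientations in degrees, each in
#'   `[0, 180)`; vectorized.
#' @return absolute differences in `[0, 180)`.
#' @export
theta_angle <- function(phi_1, phi_2) {
  if (any(phi_1 < 0 | phi_1 >= 180 | phi_2 < 0 | phi_2 >= 180))
    stop("phi must be in [0, 180) degrees")
  abs(phi_1 - phi_2)
}

#' Shared box-counting grid for one or two ellipses
#'
#' A deterministic resolution x resolution grid over the joint bounding box
#' of the supplied ellipses, expanded by `expand` (default 2%). Areas are
#' estimated by counting grid-cell centers inside an ellipse; using one
#' common grid for both ellipses and their intersection keeps the three
#' estimates consistent.
#'
#' @param geometries list of one or more `ellipse_geometry` objects.
#' @param resolution cells per axis (>= 64; default 512).
#' @param expand fractional bounding-box expansion.
#' @return list of class `box_grid` with cell-center coordinates and cell
#'   area.
#' @export
box_grid <- function(geometries, resolution = 512L, expand = 0.02) {
  if (!is.null(geometries$semi_major)) geometries <- list(geometries)
  resolution <- as.integer(resolution)
  if (resolution < 64L) stop("resolution must be >= 64")
  bb <- sapply(geometries, function(g) {
    t <- g$phi * pi / 180
    hw <- sqrt(g$semi_major^2 * cos(t)^2 + g$semi_minor^2 * sin(t)^2)
    hh <- sqrt(g$semi_major^2 * sin(t)^2 + g$semi_minor^2 * cos(t)^2)
    c(g$center[1L] - hw, g$center[1L] + hw, g$center[2L] - hh, g$center[2L] + hh)
  })
  xr <- c(min(bb[1L, ]), max(bb[2L, ]))
  yr <- c(min(bb[3L, ]), max(bb[4L, ]))
  xr <- xr + c(-1, 1) * expand * diff(xr)
  yr <- yr + c(-1, 1) * expand * diff(yr)
  dx <- diff(xr) / resolution
  dy <- diff(yr) / resolution
  structure(
    list(resolution = resolution, xrange = xr, yrange = yr,
         xc = xr[1L] + (seq_len(resolution) - 0.5) * dx,
         yc = yr[1L] + (seq_len(resolution) - 0.5) * dy,
         cell_area = dx * dy),
    class = "box_grid"
  )
}

# logical vector over the grid: cell centers inside the ellipse
grid_inside <- function(grid, g) {
  t <- g$phi * pi / 180
  ct <- cos(t); st <- sin(t)
  x <- rep(grid$xc, times = grid$resolution) - g$center[1L]
  y <- rep(grid$yc, each = grid$resolution) - g$center[2L]
  u <- (x * ct + y * st) / g$semi_major
  v <- (-x * st + y * ct) / g$semi_minor
  u * u + v * v <= 1
}

#' Box-counted area of an ellipse
#'
#' `(number of grid-cell centers inside) x (cell area)`. The error vanishes
#' as the resolution grows; at the default 512 the error against the closed
#' form `pi * A * B` is below 1%.
#'
#' @param geometry an `ellipse_geometry`.
#' @param grid a [box_grid()]; it must contain the ellipse.
#' @export
ellipse_area_boxcount <- function(geometry, grid) {
  g <- validate_geometry(geometry)
  t <- g$phi * pi / 180
  hw <- sqrt(g$semi_major^2 * cos(t)^2 + g$semi_minor^2 * sin(t)^2)
  hh <- sqrt(g$semi_major^2 * sin(t)^2 + g$semi_minor^2 * cos(t)^2)
  if (g$center[1L] - hw < grid$xrange[1L] || g$center[1L] + hw > grid$xrange[2L] ||
      g$center[2L] - hh < grid$yrange[1L] || g$center[2L] + hh > grid$yrange[2L])
    stop("grid does not contain the ellipse")
  sum(grid_inside(grid, g)) * grid$cell_area
}

#' Sorensen-Dice overlap of two ellipses
#'
#' `omega = 2 |A intersect B| / (|A| + |B|)`, all three areas box-counted on
#' the same grid, so the estimate is symmetric and lands in `[0, 1]`. The
#' standard Sorensen-Dice denominator is the *sum* of the two areas; a
#' Jaccard variant (`denominator = "union"`) is provided for comparison.
#'
#' @param geom_1,geom_2 `ellipse_geometry` objects.
#' @param resolution grid resolution per axis (default 512).
#' @param denominator `"sum"` (Dice, default) or `"union"` (Jaccard).
#' @param grid optional precomputed [box_grid()] covering both ellipses.
#' @return list with `omega`, `area_1`, `area_2`, `area_intersection`.
#' @export
omega_overlap <- function(geom_1, geom_2, resolution = 512L,
                          denominator = c("sum", "union"), grid = NULL) {
  denominator <- match.arg(denominator)
  g1 <- validate_geometry(geom_1); g2 <- validate_geometry(geom_2)
  if (is.null(grid)) grid <- box_grid(list(g1, g2), resolution)
  in1 <- grid_inside(grid, g1)
  in2 <- grid_inside(grid, g2)
  a1 <- sum(in1) * grid$cell_area
  a2 <- sum(in2) * grid$cell_area
  ai <- sum(in1 & in2) * grid$cell_area
  om <- if (denominator == "sum") {
    if (a1 + a2 == 0) 0 else 2 * ai / (a1 + a2)
  } else {
    au <- sum(in1 | in2) * grid$cell_area
    if (au == 0) 0 else ai / au
  }
  list(omega = min(max(om, 0), 1), area_1 = a1, area_2 = a2,
       area_intersection = ai)
}

#' Classify the modality scenario of a gene
#'
#' The 2x2 scheme crossing small/large angle difference with small/large
#' overlap:
#'
#' | scenario | overlap | angle |
#' |----------|---------|-------|
#' | 1        | small   | small |
#' | 2        | small   | large |
#' | 3        | large   | small |
#' | 4        | large   | large |
#'
#' The angle is "large" iff `theta_thr < theta < 180 - theta_thr`
#' (matching the DAG relevance window); the overlap is "large" iff
#' `omega >= omega_thr`. `omega_thr = 0.5` is a package convention — the
#' published analyses show the omega distributions but print no cutover.
#'
#' @param theta angle difference in degrees (vectorized).
#' @param omega overlap in `[0, 1]` (vectorized).
#' @param theta_thr angle threshold in degrees (default 10).
#' @param omega_thr overlap threshold (default 0.5).
#' @return integer scenario 1-4.
#' @export
classify_modality <- function(theta, omega, theta_thr = 10, omega_thr = 0.5) {
  large_angle <- theta > theta_thr & theta < (180 - theta_thr)
  large_overlap <- omega >= omega_thr
  ifelse(large_overlap,
         ifelse(large_angle, 4L, 3L),
         ifelse(large_angle, 2L, 1L))
}

#' Per-gene pair statistics from two phenotype fits
#'
#' Combines two `ellipse_fit`s of the same gene (one per phenotype) into
#' the derived statistics: theta, omega, box-counted areas, semi-axis
#' ratios and the modality scenario.
#'
#' @param fit_1,fit_2 `ellipse_fit` objects.
#' @param gene_id gene identifier for the output row.
#' @param resolution omega grid resolution.
#' @param theta_thr,omega_thr classifier thresholds, see
#'   [classify_modality()].
#' @return one-row data.frame with columns `gene`, `theta`, `omega`,
#'   `area_1`, `area_2`, `area_intersection`, `axis_ratio_1`,
#'   `axis_ratio_2`, `major_len_1`, `major_len_2`, `phi_1`, `phi_2`,
#'   `scenario`.
#' @export
pair_stats <- function(fit_1, fit_2, gene_id = NA_character_,
                       resolution = 512L, theta_thr = 10, omega_thr = 0.5) {
  g1 <- fit_1$geometry; g2 <- fit_2$geometry
  th <- theta_angle(g1$phi, g2$phi)
  ov <- omega_overlap(g1, g2, resolution)
  data.frame(
    gene = gene_id, theta = th, omega = ov$omega,
    area_1 = ov$area_1, area_2 = ov$area_2,
    area_intersection = ov$area_intersection,
    axis_ratio_1 = g1$semi_major / g1$semi_minor,
    axis_ratio_2 = g2$semi_major / g2$semi_minor,
    major_len_1 = 2 * g1$semi_major, major_len_2 = 2 * g2$semi_major,
    phi_1 = g1$phi, phi_2 = g2$phi,
    scenario = classify_modality(th, ov$omega, theta_thr, omega_thr),
    stringsAsFactors = FALSE
  )
}
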