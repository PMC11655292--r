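#' Fit an ellipse to a 2-D point cloud
#'
#' The central model of the package: per gene and phenotype, cells form a
#' cloud in the (mature, nascent) phase plane which is summarized by a
#' least-squares ellipse. Two strategies are available:
#'
#' * `"free"` — the direct least-squares conic fit with the ellipse-specific
#'   constraint `4ac - b^2 = 1` (Fitzgibbon's formulation), solved through
#'   the numerically stable 3x3 reduced eigensystem of Halir and Flusser.
#'   The design matrix is split into quadratic and linear blocks
#'   `D1 = [x^2, xy, y^2]`, `D2 = [x, y, 1]`; the constrained generalized
#'   eigenproblem `S a = lambda C a` then reduces to an ordinary 3x3
#'   eigenproblem whose unique eigenvector with `4 a1 a3 - a2^2 > 0` gives
#'   the quadratic coefficients, the linear ones following by
#'   back-substitution.
#' * `"origin_axis"` — an ellipse whose major-axis line is forced through
#'   the origin, encoding the steady-state assumption of the RNA-velocity
#'   phase plane. Parametrized as `(phi, t, A, B)` with center
#'   `t * (cos phi, sin phi)` and optimized by Nelder-Mead on the geometric
#'   fit error, initialized from the free fit. Its error is never below the
#'   free fit's on the same points (a constrained optimum).
#'
#' @param points n x 2 numeric matrix of (x, y) coordinates; at least 6
#'   non-degenerate points are required (6 = number of conic coefficients).
#' @param strategy `"free"` or `"origin_axis"`.
#' @param rmsd_points optional n x 2 matrix on which the fit error is
#'   evaluated instead of `points` (used to score on un-jittered coordinates
#'   while fitting jittered ones).
#' @param rmsd_method `"mean_abs"` (default) or `"rms"`, see [rmsd_of_fit()].
#' @param refine logical (free strategy only): polish the algebraic solution
#'   by direct Nelder-Mead minimization of the geometric fit error over
#'   center, orientation and semi-axes. The algebraic fit minimizes the
#'   constrained algebraic distance, which on noisy clouds is close to, but
#'   not exactly, the geometric optimum; refinement closes that gap at
#'   roughly a hundredfold cost, and is what makes the free fit comparable
#'   like-for-like with the geometrically optimized origin-axis strategy.
#' @return an object of class `ellipse_fit`: list with `conic` (named
#'   `a..f`, scaled so `4ac - b^2 = 1`), `geometry` ([conic_to_geometry()]
#'   output), `rmsd`, `rmsd_method`, `n_points`, `strategy` and the fitting
#'   `points` (for methods).
#' @examples
#' g <- list(center = c(0.5, 0.5), semi_major = 0.4, semi_minor = 0.1, phi = 30)
#' fit <- fit_ellipse(ellipse_points(g, seq(0, 2 * pi, length.out = 61)[-61]))
#' fit$geometry$phi
#' @export
fit_ellipse <- function(points, strategy = c("free", "origin_axis"),
                        rmsd_points = NULL,
                        rmsd_method = c("mean_abs", "rms"),
                        refine = FALSE) {
  strategy <- match.arg(strategy)
  rmsd_method <- match.arg(rmsd_method)
  points <- as_points(points)
  if (nrow(points) < 6L)
    stop("insufficient points for conic fit (need >= 6, got ", nrow(points), ")")
  if (strategy == "free") {
    conic <- fit_conic_direct(points[, 1L], points[, 2L])
    geometry <- conic_to_geometry(conic)
    if (refine) {
      geometry <- refine_free_fit(points, geometry, rmsd_method)
      conic <- normalize_conic(geometry_to_conic(geometry))
    }
  } else {
    res <- fit_origin_axis(points, rmsd_method)
    geometry <- res$geometry
    conic <- normalize_conic(geometry_to_conic(geometry))
  }
  sp <- if (is.null(rmsd_points)) points else as_points(rmsd_points)
  structure(
    list(conic = conic, geometry = geometry,
         rmsd = rmsd_of_fit(sp, geometry, rmsd_method),
         rmsd_method = rmsd_method, n_points = nrow(points),
         strategy = strategy, points = points),
    class = "ellipse_fit"
  )
}

as_points <- function(points) {
  points <- as.matrix(points)
  storage.mode(points) <- "double"
  if (ncol(points) != 2L) stop("points must be an n x 2 matrix")
  if (!all(is.finite(points))) stop("points must be finite")
  points
}

# Halir-Flusser reduced system for the Fitzgibbon constrained conic fit.
fit_conic_direct <- function(x, y) {
  # center the data for conditioning; shift the conic back afterwards
  mx <- mean(x); my <- mean(y)
  xs <- x - mx; ys <- y - my
  D1 <- cbind(xs^2, xs * ys, ys^2)
  D2 <- cbind(xs, ys, 1)
  S1 <- crossprod(D1)
  S2 <- crossprod(D1, D2)
  S3 <- crossprod(D2)
  T <- tryCatch(-solve(S3, t(S2)),
                error = function(e) stop("degenerate input: singular scatter matrix"))
  M <- S1 + S2 %*% T
  M <- rbind(M[3L, ] / 2, -M[2L, ], M[1L, ] / 2)   # C1^{-1} M
  ev <- eigen(M)
  vec <- ev$vectors
  if (is.complex(vec)) {
    keep <- abs(Im(ev$values)) < 1e-8 * (abs(Re(ev$values)) + 1)
    vec <- Re(vec[, keep, drop = FALSE])
  }
  if (ncol(vec) == 0L) stop("ellipse fit failed: no real eigenvector")
  cond <- 4 * vec[1L, ] * vec[3L, ] - vec[2L, ]^2
  k <- which(cond > 0)
  if (length(k) == 0L)
    stop("degenerate input: no ellipse solution (collinear or conic-degenerate points)")
  a1 <- vec[, k[1L]]
  a <- c(a1, drop(T %*% a1))
  # undo the centering shift: substitute x -> x - mx, y -> y - my
  A <- a[1L]; B <- a[2L]; C <- a[3L]; D <- a[4L]; E <- a[5L]; F <- a[6L]
  conic <- c(
    a = A, b = B, c = C,
    d = D - 2 * A * mx - B * my,
    e = E - B * mx - 2 * C * my,
    f = F + A * mx^2 + B * mx * my + C * my^2 - D * mx - E * my
  )
  normalize_conic(conic)
}

# scale so that a'Ca = 4ac - b^2 = 1, with a > 0
normalize_conic <- function(conic) {
  s <- 4 * conic[1L] * conic[3L] - conic[2L]^2
  if (s <= 0) stop("not an ellipse: 4ac - b^2 <= 0")
  conic <- conic / sqrt(s)
  if (conic[1L] < 0) conic <- -conic
  names(conic) <- c("a", "b", "c", "d", "e", "f")
  conic
}

# Nelder-Mead polish of the geometric fit error over (x0, y0, phi, log A, log B),
# with restarts (simplex collapse recovery) and an axis-ratio guard that keeps
# the search inside the sane ellipse domain
refine_free_fit <- function(points, g0, rmsd_method) {
  objective <- function(par) {
    A <- exp(par[4L]); B <- exp(par[5L])
    if (!is.finite(A) || !is.finite(B) || A < B || A / B > 20) return(1e10)
    g <- list(center = par[1:2], semi_major = A, semi_minor = B,
              phi = (par[3L] * 180 / pi) %% 180)
    rmsd_of_fit(points, g, rmsd_method)
  }
  p_alg <- c(g0$center, g0$phi * pi / 180,
             log(g0$semi_major), log(g0$semi_minor))
  # the mean-absolute error has multiple basins: probe the perpendicular
  # orientation, progressively elongated variants (long flat ellipses can
  # hug an elongated cloud) and the center-direction orientation (the basin
  # the origin-constrained strategy searches), besides the algebraic
  # solution itself
  phi_ctr <- atan2(g0$center[2L], g0$center[1L])
  starts <- list(p_alg,
                 p_alg + c(0, 0, pi / 2, 0, 0),
                 p_alg + c(0, 0, 0, log(1.5), -log(1.5)),
                 p_alg + c(0, 0, 0, log(2.5), 0),
                 p_alg + c(0, 0, 0, log(5), 0),
                 c(p_alg[1:2], phi_ctr, p_alg[4:5]))
  # the origin-constrained optimum is itself a feasible free ellipse; using
  # it as a start makes the refined free fit at least as good as the
  # constrained strategy by construction
  g_or <- tryCatch(fit_origin_axis(points, rmsd_method)$geometry,
                   error = function(e) NULL)
  if (!is.null(g_or))
    starts <- c(starts, list(c(g_or$center, g_or$phi * pi / 180,
                               log(g_or$semi_major), log(g_or$semi_minor))))
  best <- list(par = p_alg, value = objective(p_alg))
  for (p0 in starts) {
    cur <- list(par = p0, value = objective(p0))
    for (round in 1:3) {
      opt <- stats::optim(cur$par, objective, method = "Nelder-Mead",
                          control = list(maxit = 500, reltol = 1e-10))
      improved <- opt$value < cur$value - 1e-14
      if (opt$value < cur$value) cur <- opt
      if (!improved) break
    }
    if (cur$value < best$value) best <- cur
  }
  if (best$value >= 1e10) return(g0)      # polish failed, keep the algebraic fit
  A <- exp(best$par[4L]); B <- exp(best$par[5L])
  phid <- (best$par[3L] * 180 / pi) %% 180
  near <- (A - B) <= 1e-9 * A
  if (near) phid <- 0
  g1 <- structure(list(center = best$par[1:2], semi_major = A, semi_minor = B,
                       phi = phid, near_circular = near),
                  class = "ellipse_geometry")
  # never return something worse than the algebraic solution
  if (rmsd_of_fit(points, g1, rmsd_method) <=
      rmsd_of_fit(points, g0, rmsd_method)) g1 else g0
}

# geometric-error fit with the major-axis line through the origin
fit_origin_axis <- function(points, rmsd_method) {
  free <- tryCatch(fit_ellipse(points, "free", rmsd_method = rmsd_method),
                   error = function(e) NULL)
  objective <- function(par) {
    phi <- par[1L]; t <- par[2L]; A <- exp(par[3L]); B <- exp(par[4L])
    if (!is.finite(A) || !is.finite(B) || A < B || A / B > 20) return(1e10)
    g <- list(center = t * c(cos(phi), sin(phi)),
              semi_major = A, semi_minor = B,
              phi = (phi * 180 / pi) %% 180)
    rmsd_of_fit(points, g, rmsd_method)
  }
  starts <- list()
  if (!is.null(free)) {
    gf <- free$geometry
    # center direction start: representable exactly
    phi0 <- atan2(gf$center[2L], gf$center[1L])
    starts[[1L]] <- c(phi0, sqrt(sum(gf$center^2)),
                      log(gf$semi_major), log(gf$semi_minor))
    # major-axis orientation start, center projected onto that line
    phi1 <- gf$phi * pi / 180
    t1 <- sum(gf$center * c(cos(phi1), sin(phi1)))
    starts[[2L]] <- c(phi1, t1, log(gf$semi_major), log(gf$semi_minor))
  } else {
    ctr <- colMeans(points)
    s <- apply(points, 2L, stats::sd)
    starts[[1L]] <- c(atan2(ctr[2L], ctr[1L]), sqrt(sum(ctr^2)),
                      log(max(s) * 2), log(max(min(s), 1e-3)))
  }
  best <- NULL
  for (p0 in starts) {
    opt <- stats::optim(p0, objective, method = "Nelder-Mead",
                        control = list(maxit = 800, reltol = 1e-10))
    if (is.null(best) || opt$value < best$value) best <- opt
  }
  if (!is.finite(best$value) || best$value >= 1e10)
    stop("origin-axis fit failed to converge")
  phi <- best$par[1L]; t <- best$par[2L]
  A <- exp(best$par[3L]); B <- exp(best$par[4L])
  phid <- (phi * 180 / pi) %% 180
  if ((A - B) <= 1e-9 * A) phid <- 0       # circle tie-break
  g <- structure(
    list(center = t * c(cos(phi), sin(phi)), semi_major = A, semi_minor = B,
         phi = phid, near_circular = (A - B) <= 1e-9 * A),
    class = "ellipse_geometry"
  )
  list(geometry = g, value = best$value)
}

#' @export
print.ellipse_fit <- function(x, digits = 4, ...) {
  cat(sprintf("Ellipse fit (%s strategy), %d points\n", x$strategy, x$n_points))
  print(x$geometry, digits = digits)
  cat(sprintf("fit error (%s): %s\n", x$rmsd_method, format(x$rmsd, digits = digits)))
  invisible(x)
}

#' @export
summary.ellipse_fit <- function(object, ...) {
  r <- residuals(object)
  structure(list(fit = object, conic = object$conic,
                 resid_summary = summary(abs(r)),
                 axis_ratio = object$geometry$semi_major / object$geometry$semi_minor),
            class = "summary.ellipse_fit")
}

#' @export
print.summary.ellipse_fit <- function(x, digits = 4, ...) {
  print(x$fit, digits = digits)
  cat(sprintf("axis ratio: %s\n", format(x$axis_ratio, digits = digits)))
  cat("conic (a..f, scaled to 4ac - b^2 = 1):\n")
  print(round(x$conic, digits + 2))
  cat("absolute perimeter distances:\n")
  print(x$resid_summary, digits = digits)
  invisible(x)
}

#' @export
coef.ellipse_fit <- function(object, ...) object$conic

#' Signed residuals of an ellipse fit
#'
#' Perimeter distance of each fitting point, signed negative for points
#' inside the ellipse and positive outside.
#' @param object an `ellipse_fit`.
#' @param ... unused.
#' @export
residuals.ellipse_fit <- function(object, ...) {
  d <- point_ellipse_distance(object$points, object$geometry)
  conic <- object$conic
  x <- object$points[, 1L]; y <- object$points[, 2L]
  v <- conic[1L] * x^2 + conic[2L] * x * y + conic[3L] * y^2 +
    conic[4L] * x + conic[5L] * y + conic[6L]
  # conic is negative inside (a > 0 normalization)
  d * ifelse(v < 0, -1, 1)
}

#' Predict perimeter points of a fitted ellipse
#'
#' @param object an `ellipse_fit`.
#' @param t parametric angles in radians (default: 200 points around the
#'   perimeter).
#' @param ... unused.
#' @return n x 2 matrix of perimeter coordinates.
#' @export
predict.ellipse_fit <- function(object, t = seq(0, 2 * pi, length.out = 201L)[-201L], ...) {
  ellipse_points(object$geometry, t)
}

#' Plot an ellipse fit over its points
#'
#' @param x an `ellipse_fit`.
#' @param add logical; add to an existing plot.
#' @param col_points,col_ellipse colors.
#' @param ... passed to [graphics::plot()].
#' @export
plot.ellipse_fit <- function(x, add = FALSE, col_points = "grey40",
                             col_ellipse = "firebrick", ...) {
  per <- predict(x)
  if (!add) {
    rng_x <- range(c(x$points[, 1L], per[, 1L]))
    rng_y <- range(c(x$points[, 2L], per[, 2L]))
    graphics::plot(x$points, pch = 16, cex = 0.5, col = col_points,
                   xlim = rng_x, ylim = rng_y,
                   xlab = "mature", ylab = "nascent", ...)
  } else {
    graphics::points(x$points, pch = 16, cex = 0.5, col = col_points)
  }
  graphics::lines(rbind(per, per[1L, , drop = FALSE]), col = col_ellipse, lwd = 2)
  invisible(x)
}
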