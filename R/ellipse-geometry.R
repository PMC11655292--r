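#' Convert conic coefficients to ellipse geometry
#'
#' A conic `a x^2 + b xy + c y^2 + d x + e y + f = 0` describes an ellipse
#' exactly when its discriminant `b^2 - 4ac` is negative. This function
#' recovers the geometric parametrization: center, semi-axes and the
#' orientation `phi` of the major axis.
#'
#' The orientation follows the standard half-angle relation
#' `phi = 1/2 * atan2(b, a - c)`, disambiguated so that `phi` always refers
#' to the major axis (via the eigenvectors of the quadratic form). Angles are
#' reported in degrees in `[0, 180)`. When the two semi-axes agree to within
#' `1e-9` (relative), the orientation is undefined; by convention `phi` is set
#' to 0 and the geometry is flagged `near_circular`.
#'
#' @param conic numeric vector of length 6, named or in the order
#'   `a, b, c, d, e, f`.
#' @return an object of class `ellipse_geometry`: a list with `center`
#'   (length-2 numeric), `semi_major`, `semi_minor`, `phi` (degrees in
#'   `[0,180)`) and logical `near_circular`.
#' @seealso [geometry_to_conic()] for the inverse, [fit_ellipse()].
#' @export
conic_to_geometry <- function(conic) {
  conic <- as.numeric(conic)
  if (length(conic) != 6L || !all(is.finite(conic)))
    stop("conic must be 6 finite coefficients (a, b, c, d, e, f)")
  a <- conic[1]; b <- conic[2]; cc <- conic[3]
  d <- conic[4]; e <- conic[5]; f <- conic[6]
  disc <- b^2 - 4 * a * cc
  if (disc >= 0)
    stop("not an ellipse: discriminant b^2 - 4ac = ", format(disc), " >= 0")

  # center solves the gradient system [2a b; b 2c] (x,y)' = -(d,e)'
  Q <- matrix(c(2 * a, b, b, 2 * cc), 2L, 2L)
  center <- drop(solve(Q, -c(d, e)))
  # conic value at the center; proper ellipse requires sign opposite to a
  fc <- a * center[1]^2 + b * center[1] * center[2] + cc * center[2]^2 +
    d * center[1] + e * center[2] + f
  A2 <- matrix(c(a, b / 2, b / 2, cc), 2L, 2L)
  ev <- eigen(A2, symmetric = TRUE)        # values in decreasing order
  ax <- -fc / ev$values                    # squared semi-axes
  if (any(ax <= 0))
    stop("degenerate conic: non-positive squared semi-axis")
  ax <- sqrt(ax)                           # increasing axis for decreasing value
  semi_minor <- ax[1]; semi_major <- ax[2]
  near_circular <- (semi_major - semi_minor) <= 1e-9 * semi_major
  if (near_circular) {
    phi <- 0
  } else {
    v <- ev$vectors[, 2L]                  # eigenvector of smaller eigenvalue = major axis
    phi <- atan2(v[2L], v[1L]) * 180 / pi
    phi <- phi %% 180
    if (phi >= 180) phi <- phi - 180
  }
  structure(
    list(center = unname(center), semi_major = semi_major,
         semi_minor = semi_minor, phi = phi, near_circular = near_circular),
    class = "ellipse_geometry"
  )
}

#' Convert ellipse geometry to conic coefficients
#'
#' Inverse of [conic_to_geometry()]. The returned coefficients are scaled so
#' that the conic equals `-1` at the center (i.e. `f` absorbs the `-1` of the
#' canonical form), and satisfy `b^2 - 4ac < 0`.
#'
#' @param geometry an `ellipse_geometry`, or a list with `center`,
#'   `semi_major`, `semi_minor`, `phi` (degrees).
#' @return named numeric vector `c(a, b, c, d, e, f)`.
#' @export
geometry_to_conic <- function(geometry) {
  g <- validate_geometry(geometry)
  x0 <- g$center[1]; y0 <- g$center[2]
  A <- g$semi_major; B <- g$semi_minor
  t <- g$phi * pi / 180
  ct <- cos(t); st <- sin(t)
  a <- ct^2 / A^2 + st^2 / B^2
  b <- 2 * ct * st * (1 / A^2 - 1 / B^2)
  cc <- st^2 / A^2 + ct^2 / B^2
  d <- -(2 * a * x0 + b * y0)
  e <- -(b * x0 + 2 * cc * y0)
  f <- a * x0^2 + b * x0 * y0 + cc * y0^2 - 1
  c(a = a, b = b, c = cc, d = d, e = e, f = f)
}

validate_geometry <- function(geometry) {
  if (!is.list(geometry) ||
      !all(c("center", "semi_major", "semi_minor", "phi") %in% names(geometry)))
    stop("geometry must have center, semi_major, semi_minor and phi")
  if (geometry$semi_major < geometry$semi_minor)
    stop("semi_major must be >= semi_minor")
  if (geometry$semi_minor <= 0) stop("semi-axes must be positive")
  geometry
}

#' @export
print.ellipse_geometry <- function(x, digits = 4, ...) {
  cat(sprintf(
    "ellipse: center (%s, %s), semi-axes (%s, %s), phi %s deg%s\n",
    format(x$center[1], digits = digits), format(x$center[2], digits = digits),
    format(x$semi_major, digits = digits), format(x$semi_minor, digits = digits),
    format(x$phi, digits = digits),
    if (isTRUE(x$near_circular)) " (near-circular)" else ""
  ))
  invisible(x)
}

#' Distance from points to an ellipse perimeter
#'
#' Euclidean distance from each point to the nearest point on the ellipse
#' boundary (the foot point), for points inside or outside the ellipse.
#' Points are first mapped into the ellipse frame; the first-quadrant
#' foot-point equation is then solved by safeguarded bisection on
#' Eberly's scalar root function, which is monotone on its bracket, giving
#' better than `1e-8` relative accuracy.
#'
#' @param points numeric matrix (n x 2) or length-2 vector.
#' @param geometry an `ellipse_geometry`.
#' @return numeric vector of non-negative distances, one per point.
#' @export
point_ellipse_distance <- function(points, geometry) {
  g <- validate_geometry(geometry)
  if (is.null(dim(points))) points <- matrix(points, ncol = 2L)
  points <- as.matrix(points)
  if (ncol(points) != 2L) stop("points must be n x 2")
  t <- g$phi * pi / 180
  # rows are points: right-multiplying by this matrix applies R(-phi),
  # mapping world coordinates into the ellipse frame
  R <- matrix(c(cos(t), sin(t), -sin(t), cos(t)), 2L, 2L)
  q <- sweep(points, 2L, g$center) %*% R
  qx <- abs(q[, 1L]); qy <- abs(q[, 2L])
  A <- g$semi_major; B <- g$semi_minor

  if ((A - B) <= 1e-12 * A) {              # circle: closed form
    return(abs(sqrt(qx^2 + qy^2) - A))
  }

  d <- numeric(length(qx))
  ey <- qy > 1e-14 * B
  ex <- !ey
  if (any(ex)) {                           # on the major axis: closed form
    x <- qx[ex]
    crit <- (A^2 - B^2) / A
    inner <- x < crit
    di <- numeric(length(x))
    if (any(inner)) {
      fx <- A^2 * x[inner] / (A^2 - B^2)
      fy <- B * sqrt(pmax(0, 1 - (fx / A)^2))
      di[inner] <- sqrt((fx - x[inner])^2 + fy^2)
    }
    di[!inner] <- abs(x[!inner] - A)
    d[ex] <- di
  }
  if (any(ey)) {
    x <- qx[ey]; y <- qy[ey]
    # root of F(s) = (A x / (s + A^2))^2 + (B y / (s + B^2))^2 - 1, s > -B^2.
    # F is convex and decreasing, so Newton from the left bracket endpoint
    # (where F >= 0) converges monotonically without overshoot.
    s <- -B^2 + B * y
    ax2 <- (A * x)^2; by2 <- (B * y)^2
    for (i in seq_len(30L)) {
      u <- s + A^2; v <- s + B^2
      Fv <- ax2 / u^2 + by2 / v^2 - 1
      dF <- -2 * (ax2 / u^3 + by2 / v^3)
      step <- Fv / dF
      s <- s - step
      if (max(abs(step)) < 1e-14 * (B^2 + max(abs(s)))) break
    }
    fx <- A^2 * x / (s + A^2)
    fy <- B^2 * y / (s + B^2)
    d[ey] <- sqrt((fx - x)^2 + (fy - y)^2)
  }
  d
}

#' Goodness of fit of an ellipse to a point cloud
#'
#' The fit error statistic used for gene filtering: by default the mean of
#' the absolute point-to-perimeter distances (the convention under which the
#' field reports "RMSD" for these fits), with a true root-mean-square option.
#' It must be computed on un-jittered, min-max-normalized coordinates.
#'
#' @param points n x 2 matrix.
#' @param geometry an `ellipse_geometry`.
#' @param method `"mean_abs"` (default) or `"rms"`.
#' @return single non-negative number.
#' @export
rmsd_of_fit <- function(points, geometry, method = c("mean_abs", "rms")) {
  method <- match.arg(method)
  if (is.null(dim(points))) points <- matrix(points, ncol = 2L)
  if (nrow(points) == 0L) stop("empty point set")
  d <- point_ellipse_distance(points, geometry)
  if (method == "mean_abs") mean(d) else sqrt(mean(d^2))
}

#' Points on an ellipse perimeter
#'
#' Parametric perimeter samples, used for plotting and for generating
#' noiseless test ellipses.
#'
#' @param geometry an `ellipse_geometry` (or compatible list).
#' @param t angles (radians) of the parametric form; default 200 equally
#'   spaced values on `[0, 2*pi)`.
#' @return n x 2 matrix of coordinates.
#' @export
ellipse_points <- function(geometry, t = seq(0, 2 * pi, length.out = 201L)[-201L]) {
  g <- validate_geometry(geometry)
  ph <- g$phi * pi / 180
  x <- g$semi_major * cos(t)
  y <- g$semi_minor * sin(t)
  cbind(
    g$center[1] + x * cos(ph) - y * sin(ph),
    g$center[2] + x * sin(ph) + y * cos(ph)
  )
}
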