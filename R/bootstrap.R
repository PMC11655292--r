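#' Bootstrap an ellipse fit
#'
#' Assesses stability of the fitted orientation and area. Each replicate
#' resamples the points with replacement (optional) and adds independent
#' uniform jitter in `[-eps, eps]` to every coordinate — the jitter both
#' mirrors the singularity-avoiding jitter applied before fitting and makes
#' replicates distinct when resampling is disabled. `eps` is interpreted on
#' the scale of the supplied coordinates; the conventional `eps = 0.5` is a
#' half count on the raw count scale (rescale it accordingly when
#' bootstrapping min-max-normalized clouds).
#'
#' Replicates whose fit fails (degenerate resample) are counted, not
#' imputed; more than 50% failures aborts with an instability error.
#'
#' @param points n x 2 matrix.
#' @param n_boot number of replicates (the conventional default is 1000).
#' @param eps jitter amplitude; `0` disables jitter.
#' @param seed integer seed for reproducibility; `NULL` leaves the RNG state
#'   alone.
#' @param resample logical; resample cells with replacement (default TRUE).
#'   With `resample = FALSE` and `eps = 0` every replicate equals the point
#'   fit.
#' @param level confidence level of the percentile interval for `phi`.
#' @return object of class `bootstrap_summary`: `n_boot`, `fail_count`,
#'   `phi_samples`, `area_samples` (length `n_boot - fail_count`),
#'   `phi_point` (fit on the original points), `phi_ci`, `area_ci`.
#' @export
bootstrap_fit <- function(points, n_boot = 1000L, eps = 0.5, seed = NULL,
                          resample = TRUE, level = 0.95) {
  points <- as_points(points)
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(points)
  phi <- area <- numeric(n_boot)
  ok <- logical(n_boot)
  for (i in seq_len(n_boot)) {
    idx <- if (resample) sample.int(n, n, replace = TRUE) else seq_len(n)
    p <- points[idx, , drop = FALSE]
    if (eps > 0)
      p <- p + matrix(stats::runif(2L * n, -eps, eps), n, 2L)
    fit <- tryCatch(fit_ellipse(p, "free"), error = function(e) NULL)
    if (!is.null(fit)) {
      ok[i] <- TRUE
      phi[i] <- fit$geometry$phi
      area[i] <- pi * fit$geometry$semi_major * fit$geometry$semi_minor
    }
  }
  fail_count <- sum(!ok)
  if (fail_count > n_boot / 2)
    stop("unstable bootstrap: ", fail_count, " of ", n_boot, " replicate fits failed")
  point_fit <- fit_ellipse(points, "free")
  alpha <- (1 - level) / 2
  phi_s <- phi[ok]; area_s <- area[ok]
  structure(
    list(n_boot = n_boot, fail_count = fail_count,
         phi_samples = phi_s, area_samples = area_s,
         phi_point = point_fit$geometry$phi,
         phi_ci = unname(stats::quantile(phi_s, c(alpha, 1 - alpha), type = 7)),
         area_ci = unname(stats::quantile(area_s, c(alpha, 1 - alpha), type = 7)),
         level = level),
    class = "bootstrap_summary"
  )
}

#' @export
print.bootstrap_summary <- function(x, digits = 4, ...) {
  cat(sprintf("Ellipse bootstrap: %d replicates (%d failed)\n",
              x$n_boot, x$fail_count))
  cat(sprintf("phi: %s deg, %d%% CI [%s, %s]\n",
              format(x$phi_point, digits = digits), round(100 * x$level),
              format(x$phi_ci[1L], digits = digits),
              format(x$phi_ci[2L], digits = digits)))
  cat(sprintf("area: median %s, CI [%s, %s]\n",
              format(stats::median(x$area_samples), digits = digits),
              format(x$area_ci[1L], digits = digits),
              format(x$area_ci[2L], digits = digits)))
  invisible(x)
}
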