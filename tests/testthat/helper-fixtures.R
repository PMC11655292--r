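# shared fixtures, all generated in code

geom <- function(center, A, B, phi) {
  list(center = center, semi_major = A, semi_minor = B, phi = phi)
}

# noiseless parametric perimeter samples
perimeter_points <- function(center, A, B, phi, n = 60L) {
  ellipse_points(geom(center, A, B, phi),
                 t = seq(0, 2 * pi, length.out = n + 1L)[-(n + 1L)])
}

# bivariate normal cloud with covariance orientation phi (degrees) and
# axis standard deviations sds = c(major, minor)
gauss_cloud <- function(n, center, sds, phi, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  t <- phi * pi / 180
  u <- rnorm(n, sd = sds[1L]); v <- rnorm(n, sd = sds[2L])
  cbind(center[1L] + u * cos(t) - v * sin(t),
        center[2L] + u * sin(t) + v * cos(t))
}

random_geometry <- function() {
  A <- runif(1, 0.5, 2)
  ratio <- runif(1, 1.05, 20)
  geom(runif(2, -3, 3), A, A / ratio, runif(1, 0, 180))
}

# small bimodal matrix with fully controlled counts
toy_matrix <- function(nascent, mature, phenotype = NULL, batch = NULL) {
  if (is.null(phenotype)) phenotype <- rep("p1", ncol(nascent))
  bimodal_matrix(nascent, mature, phenotype = phenotype, batch = batch)
}

# closed-form Dice overlap of two unit circles at center distance d
circle_dice <- function(d, r = 1) {
  if (d >= 2 * r) return(0)
  lens <- 2 * r^2 * acos(d / (2 * r)) - (d / 2) * sqrt(4 * r^2 - d^2)
  lens / (pi * r^2)
}

# exhaustive-permutation two-sided Mann-Whitney oracle (tie-free inputs)
perm_wilcox <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  all_v <- c(x, y)
  u_obs <- sum(outer(x, y, `>`))
  combs <- utils::combn(n1 + n2, n1)
  u_perm <- apply(combs, 2L, function(idx)
    sum(outer(all_v[idx], all_v[-idx], `>`)))
  p <- 2 * min(mean(u_perm <= u_obs), mean(u_perm >= u_obs))
  list(u = u_obs, p = min(1, p))
}

# run the CLI script in a child R process
cli_run <- function(args) {
  script <- system.file("cli", "dagfit.R", package = "dagfit")
  out <- tempfile(); err <- tempfile()
  status <- suppressWarnings(system2(
    file.path(R.home("bin"), "Rscript"), c(script, args),
    stdout = out, stderr = err,
    env = paste0("R_LIBS=", paste(.libPaths(), collapse = .Platform$path.sep))
  ))
  list(status = status, stdout = readLines(out, warn = FALSE),
       stderr = readLines(err, warn = FALSE))
}
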