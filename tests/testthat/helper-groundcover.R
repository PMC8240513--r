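# Shared fixtures and independent oracles for the test suite.

# A reduced trial for fast end-to-end tests (partial replication preserved:
# 16 genotypes on 24 plots, 8 replicated -> nrep = 1.5).
small_trial_config <- function() {
  cfg <- default_config()$trial
  cfg$n_plots <- 24L
  cfg$n_genotypes <- 16L
  cfg$n_field_rows <- 4L
  cfg$n_field_cols <- 6L
  cfg
}

# Full configuration scaled down for pipeline tests.
small_config <- function() {
  cfg <- default_config()
  cfg$trial <- small_trial_config()
  cfg$rgb$image_height <- 16L
  cfg$rgb$image_width <- 20L
  cfg$lidar$n_points <- 400L
  cfg
}

high_light_event <- function() list(solar_radiation = 2.0, dew = FALSE)
dark_event <- function() list(solar_radiation = 0, dew = FALSE)
dew_event <- function() list(solar_radiation = 0.1, dew = TRUE)

# ---- brute-force oracles (independent of the vectorised implementations) --

oracle_gc_rgb <- function(image, vi_threshold = 0) {
  h <- dim(image)[1]; w <- dim(image)[2]
  n_green <- 0L
  for (i in seq_len(h)) {
    for (j in seq_len(w)) {
      r <- image[i, j, 1]; g <- image[i, j, 2]
      vi <- if (r + g == 0) 0 else (g - r) / (g + r)
      if (vi > vi_threshold) n_green <- n_green + 1L
    }
  }
  n_green / (h * w)
}

oracle_gc_rr <- function(scan, rr_threshold = 5) {
  n_veg <- 0L
  for (i in seq_len(nrow(scan))) {
    if (scan$intensity[i] < rr_threshold) n_veg <- n_veg + 1L
  }
  n_veg / nrow(scan)
}

oracle_gc_ht <- function(scan, ht_threshold = 0.10) {
  n_veg <- 0L
  for (i in seq_len(nrow(scan))) {
    if (scan$z[i] > ht_threshold) n_veg <- n_veg + 1L
  }
  n_veg / nrow(scan)
}

oracle_mean <- function(x) {
  s <- 0
  for (i in seq_along(x)) s <- s + x[i]
  s / length(x)
}

# Type-7 quantile written from its definition: with sorted x and
# h = (n - 1) p + 1, q = x[floor(h)] + (h - floor(h)) (x[floor(h)+1] - x[floor(h)]).
oracle_percentile <- function(x, p) {
  x <- sort(x)
  n <- length(x)
  h <- (n - 1) * p + 1
  lo <- floor(h)
  if (lo >= n) return(x[n])
  x[lo] + (h - lo) * (x[lo + 1] - x[lo])
}

oracle_pearson_r <- function(x, y) {
  mx <- mean(x); my <- mean(y)
  sum((x - mx) * (y - my)) /
    sqrt(sum((x - mx)^2) * sum((y - my)^2))
}

# Dense restricted log-likelihood of y = mu + genotype + row + col + eps,
# used to check that the REML fit maximises the restricted likelihood.
# d: data frame with value, genotype, row, col. s2: c(g, row, col, eps).
oracle_reml_loglik <- function(d, s2) {
  y <- d$value
  n <- length(y)
  X <- matrix(1, n, 1)
  Zg <- stats::model.matrix(~ 0 + factor(d$genotype))
  Zr <- stats::model.matrix(~ 0 + factor(d$row))
  Zc <- stats::model.matrix(~ 0 + factor(d$col))
  V <- s2[1] * tcrossprod(Zg) + s2[2] * tcrossprod(Zr) +
    s2[3] * tcrossprod(Zc) + s2[4] * diag(n)
  Vi <- solve(V)
  XtViX <- t(X) %*% Vi %*% X
  b <- solve(XtViX, t(X) %*% Vi %*% y)
  r <- y - X %*% b
  as.numeric(
    -0.5 * (determinant(V, logarithm = TRUE)$modulus +
              determinant(XtViX, logarithm = TRUE)$modulus +
              t(r) %*% Vi %*% r)
  )
}

# Random 8-bit test image with independent uniform channels.
random_image <- function(h, w, seed) {
  withr::with_seed(seed, {
    arr <- array(sample(0:255, h * w * 3, replace = TRUE), dim = c(h, w, 3))
    arr
  })
}

# A sensor bundle with controllable content for estimation tests.
make_bundle <- function(plot, event_id, images, image_positions, scan, ndvi) {
  structure(
    list(plot = plot, event_id = event_id, image_positions = image_positions,
         images = images, scan = scan, ndvi = ndvi),
    class = "sensor_bundle"
  )
}

as_scan <- function(along, cross, z, intensity) {
  s <- tibble::tibble(along_track = along, cross_track = cross,
                      z = z, intensity = intensity)
  class(s) <- c("lidar_scan", class(s))
  s
}

as_stream <- function(position, ndvi) {
  s <- tibble::tibble(position = position, ndvi = ndvi)
  class(s) <- c("ndvi_stream", class(s))
  s
}
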