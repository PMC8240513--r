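#' Greenness vegetation index
#'
#' \eqn{VI = (G - R)/(G + R)} per pixel. A pixel is classified as
#' vegetation when VI exceeds the threshold (default 0), strictly: VI equal
#' to the threshold is non-vegetation. Pixels with `green + red == 0`
#' (black) return 0 and are therefore non-vegetation.
#'
#' @param red,green Channel values (>= 0); vectorised.
#' @return Numeric VI values in \[-1, 1\].
#' @export
#' @examples
#' vegetation_index(50, 100)   # 1/3
#' vegetation_index(80, 80)    # 0: not vegetation under VI > 0
vegetation_index <- function(red, green) {
  if (any(red < 0, na.rm = TRUE) || any(green < 0, na.rm = TRUE)) {
    abort_domain("channel values must be >= 0")
  }
  s <- red + green
  ifelse(s == 0, 0, (green - red) / s)
}

#' Ground cover of a single RGB image
#'
#' The exact fraction of pixels whose greenness index exceeds
#' `config$vi_threshold`. The blue channel is ignored.
#'
#' @param image An `rgb_image` (H x W x 3 array, values 0-255).
#' @param config Estimator section of [default_config()].
#' @return Fraction in \[0, 1\].
#' @export
gc_rgb_image <- function(image, config = default_config()$estimator) {
  if (is.null(dim(image)) || length(dim(image)) != 3L || dim(image)[3] < 3L) {
    abort_domain("`image` must be an H x W x 3 array")
  }
  if (prod(dim(image)[1:2]) == 0) abort_missing("empty image")
  red <- image[, , 1]
  green <- image[, , 2]
  mean(vegetation_index(red, green) > config$vi_threshold)
}

#' Ground cover of a plot from its RGB images
#'
#' Unweighted arithmetic mean of the per-image green-pixel fractions.
#'
#' @param images Non-empty list of `rgb_image` arrays.
#' @param config Estimator section of [default_config()].
#' @return Fraction in \[0, 1\].
#' @export
gc_rgb_plot <- function(images, config = default_config()$estimator) {
  if (length(images) == 0) {
    abort_missing("no images assigned to this plot")
  }
  mean(purrr::map_dbl(images, gc_rgb_image, config = config))
}

#' Ground cover from LiDAR red reflectance
#'
#' Fraction of returns with intensity strictly below `rr_threshold`
#' (default 5). Returns at exactly the threshold are soil.
#'
#' @param scan A `lidar_scan` (pre-segmented to the sampling region).
#' @param config Estimator section of [default_config()].
#' @return Fraction in \[0, 1\].
#' @export
#' @examples
#' scan <- tibble::tibble(along_track = 0, cross_track = 0, z = 0,
#'                        intensity = c(0, 3, 4, 5, 6, 255))
#' gc_lidar_rr(scan)  # 0.5
gc_lidar_rr <- function(scan, config = default_config()$estimator) {
  if (nrow(scan) == 0) abort_missing("empty LiDAR scan")
  mean(scan$intensity < config$rr_threshold)
}

#' Normalise LiDAR heights to local ground level
#'
#' Estimates the ground level as the 5th percentile of raw z within the
#' region and subtracts it, flooring at zero. With fewer than 50 returns the
#' percentile is unreliable; a warning is raised and the minimum z is used
#' instead. Height-based GC is invariant to vertical translation of the
#' scan by construction.
#'
#' @param scan A `lidar_scan`.
#' @return The scan with `z` replaced by height above local ground.
#' @export
normalize_heights <- function(scan) {
  if (nrow(scan) == 0) abort_missing("empty LiDAR scan")
  if (nrow(scan) < 50) {
    rlang::warn("fewer than 50 returns: ground level set to minimum z",
                class = "gc_unreliable_ground")
    ground <- min(scan$z)
  } else {
    ground <- unname(quantile(scan$z, 0.05, type = 7))
  }
  scan$z <- pmax(scan$z - ground, 0)
  scan
}

#' Ground cover from LiDAR height
#'
#' Fraction of returns strictly higher than `ht_threshold` (default 0.10 m)
#' above local ground. Heights must already be normalised
#' ([normalize_heights()]); returns at exactly the threshold are ground.
#'
#' @param scan A `lidar_scan` with ground-referenced z.
#' @param config Estimator section of [default_config()].
#' @return Fraction in \[0, 1\].
#' @export
gc_lidar_ht <- function(scan, config = default_config()$estimator) {
  if (nrow(scan) == 0) abort_missing("empty LiDAR scan")
  mean(scan$z > config$ht_threshold)
}

#' Plot-mean NDVI
#'
#' Arithmetic mean of the NDVI readings assigned to the plot.
#'
#' @param stream An `ndvi_stream` (pre-assigned to the region).
#' @return Value in \[0, 0.99\].
#' @export
ndvi_plot_mean <- function(stream) {
  if (nrow(stream) == 0) abort_missing("no NDVI readings assigned to this plot")
  mean(stream$ndvi)
}

#' Sampling region of a plot
#'
#' The along-track interval excludes an `end_buffer` at each end of the
#' plot; the cross-track interval spans the inner `n_rows_per_plot - 2`
#' sown rows plus half a row spacing on each side (outermost rows excluded
#' to avoid edge effects). With the default 6 m plot, 0.5 m buffers and 7
#' rows at 0.25 m this is a 5 m by 1.25 m region. Both intervals are
#' half-open `[start, end)`.
#'
#' @param design A `trial_design`.
#' @param plot Plot identifier in the design.
#' @param config Estimator section of [default_config()].
#' @return List of class `sampling_region` with `along_start`, `along_end`,
#'   `cross_min`, `cross_max`.
#' @export
#' @examples
#' tr <- simulate_trial(default_config()$trial, seed = 1)
#' r <- sampling_region(tr$design, 1)
#' r$along_end - r$along_start  # 5
sampling_region <- function(design, plot, config = default_config()$estimator) {
  validate_estimator_config(config)
  if (!plot %in% design$plot) {
    abort_design(sprintf("plot %s is not in the trial design", plot))
  }
  len <- attr(design, "plot_length")
  spacing <- attr(design, "row_spacing")
  n_rows <- attr(design, "n_rows_per_plot")
  if (2 * config$end_buffer >= len) {
    abort_geometry("end buffers meet or exceed the plot length")
  }
  inner <- if (isTRUE(config$exclude_outer_rows)) n_rows - 2L else n_rows
  if (inner < 1) abort_geometry("no rows left after excluding the outer rows")
  half_width <- ((inner - 1) * spacing + spacing) / 2
  structure(
    list(along_start = config$end_buffer,
         along_end = len - config$end_buffer,
         cross_min = -half_width,
         cross_max = half_width),
    class = "sampling_region"
  )
}

#' Assign along-track positions to a sampling region
#'
#' Indices of positions falling in the half-open interval
#' `[along_start, along_end)`.
#'
#' @param positions Numeric along-track positions, metres.
#' @param region A `sampling_region`.
#' @return Integer index vector (possibly empty).
#' @export
assign_to_plot <- function(positions, region) {
  which(positions >= region$along_start & positions < region$along_end)
}

#' Clip a LiDAR scan to a sampling region
#'
#' Keeps returns with along-track in `[along_start, along_end)` and
#' cross-track in `[cross_min, cross_max)`.
#'
#' @param scan A `lidar_scan`.
#' @param region A `sampling_region`.
#' @return The clipped scan.
#' @export
clip_scan <- function(scan, region) {
  keep <- scan$along_track >= region$along_start &
    scan$along_track < region$along_end &
    scan$cross_track >= region$cross_min &
    scan$cross_track < region$cross_max
  scan[keep, , drop = FALSE]
}

#' Estimate all four ground-cover values for one sensor bundle
#'
#' Segments the bundle's streams to the plot's sampling region and applies
#' the four estimators. A sensor whose data is absent from the region
#' yields a flagged missing row (`value = NA`), never a silent zero.
#'
#' @param bundle A `sensor_bundle`.
#' @param design A `trial_design`.
#' @param config Estimator section of [default_config()].
#' @return Tibble with one row per method: plot, event_id, method, value,
#'   n_samples.
#' @export
estimate_bundle <- function(bundle, design, config = default_config()$estimator) {
  region <- sampling_region(design, bundle$plot, config)

  img_idx <- assign_to_plot(bundle$image_positions, region)
  rgb_val <- if (length(img_idx) > 0) {
    gc_rgb_plot(bundle$images[img_idx], config)
  } else NA_real_

  scan <- clip_scan(bundle$scan, region)
  if (nrow(scan) > 0) {
    rr_val <- gc_lidar_rr(scan, config)
    ht_val <- gc_lidar_ht(suppressWarnings(normalize_heights(scan)), config)
    n_pts <- nrow(scan)
  } else {
    rr_val <- NA_real_; ht_val <- NA_real_; n_pts <- 0L
  }

  ndvi_idx <- assign_to_plot(bundle$ndvi$position, region)
  ndvi_val <- if (length(ndvi_idx) > 0) {
    ndvi_plot_mean(bundle$ndvi[ndvi_idx, ])
  } else NA_real_

  tibble::new_tibble(
    list(
      plot = rep(bundle$plot, 4L),
      event_id = rep(bundle$event_id, 4L),
      method = gc_methods(),
      value = c(ndvi_val, rgb_val, rr_val, ht_val),
      n_samples = as.integer(c(length(ndvi_idx), length(img_idx), n_pts, n_pts))
    ),
    nrow = 4L
  )
}

#' Build the long-format GC table from sensor bundles
#'
#' One row per (plot, event, method); the central exchange object between
#' estimation and the reliability statistics. Duplicate
#' (plot, event, method) combinations are an integrity error.
#'
#' @param bundles List of `sensor_bundle` objects.
#' @param design A `trial_design`.
#' @param config Estimator section of [default_config()].
#' @return Tibble of class `gc_table`.
#' @export
build_gc_table <- function(bundles, design, config = default_config()$estimator) {
  rows <- purrr::map(bundles, estimate_bundle, design = design, config = config)
  as_gc_table(dplyr::bind_rows(rows))
}

as_gc_table <- function(df) {
  key <- paste(df$plot, df$event_id, df$method, sep = "\r")
  if (anyDuplicated(key)) {
    abort_integrity("duplicate (plot, event, method) rows in GC table")
  }
  if (!inherits(df, "gc_table")) class(df) <- c("gc_table", class(df))
  df
}
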