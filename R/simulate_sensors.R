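#' Simulate RGB plot images under a given light level
#'
#' Renders 8-bit RGB images of a plot with true ground cover `true_gc`.
#' Each pixel is vegetation with probability `true_gc`; vegetation uses a
#' green-dominant base colour and soil a red-dominant one. The rendered
#' channel is `ambient + base * exposure + noise`, rounded and clipped to
#' \[0, 255\], where exposure is `min(1, radiation / rad_full)^2`. At
#' adequate light the green-red contrast far exceeds the pixel noise and the
#' green-pixel fraction concentrates near `true_gc`; as light falls the
#' contrast sinks below the noise floor and per-pixel classification tends
#' to a coin flip. A per-image green-channel colour cast (`cast_sd`), which
#' does not scale with exposure, reproduces the image-to-image instability
#' of a passive camera in poor light.
#'
#' @param true_gc True ground cover, strictly in (0, 1).
#' @param event Sampling event (one-row schedule tibble or list with
#'   `solar_radiation` and `dew`).
#' @param n_images Number of images to render (>= 1).
#' @param image_size `c(height, width)` in pixels.
#' @param seed Integer seed; identical seeds give identical images.
#' @param config RGB section of [default_config()].
#' @return List of `rgb_image` arrays (H x W x 3, integer values 0-255).
#' @export
#' @examples
#' ev <- make_event_schedule()[1, ]
#' img <- simulate_rgb_images(0.5, ev, n_images = 1,
#'                            image_size = c(20, 30), seed = 1)[[1]]
#' dim(img)
simulate_rgb_images <- function(true_gc, event, n_images,
                                image_size = c(default_config()$rgb$image_height,
                                               default_config()$rgb$image_width),
                                seed, config = default_config()$rgb) {
  check_scalar_number(seed, "seed")
  withr::with_seed(seed, {
    rgb_images_core(true_gc, event, n_images, image_size, config)
  })
}

# RNG-consuming core; caller owns the seed scope.
rgb_images_core <- function(true_gc, event, n_images, image_size, config) {
  check_gc_fraction(true_gc)
  event <- as_event(event)
  if (n_images < 1) abort_domain("`n_images` must be >= 1")
  h <- as.integer(image_size[1]); w <- as.integer(image_size[2])
  if (h < 1 || w < 1) abort_domain("image dimensions must be >= 1")

  exposure <- min(1, event$solar_radiation / config$rad_full)^2
  npx <- h * w
  veg_col <- config$veg_rgb * exposure
  soil_col <- config$soil_rgb * exposure
  out <- vector("list", n_images)
  for (k in seq_len(n_images)) {
    veg <- runif(npx) < true_gc
    cast <- rnorm(1, 0, config$cast_sd)
    noise <- rnorm(3L * npx, 0, config$noise_sd)
    vals <- matrix(config$ambient + noise, npx, 3L)
    for (ch in 1:3) {
      col <- rep(soil_col[ch], npx)
      col[veg] <- veg_col[ch]
      vals[, ch] <- vals[, ch] + col
    }
    vals[, 2L] <- vals[, 2L] + cast
    arr <- array(round(clip(vals, 0, 255)), dim = c(h, w, 3L))
    class(arr) <- c("rgb_image", class(arr))
    out[[k]] <- arr
  }
  out
}

#' Simulate a LiDAR scan of a plot
#'
#' Draws `n_points` returns uniformly over the scanned extent. Each return
#' is vegetation with probability `true_gc`. Reflectance intensity is
#' bimodal: dry vegetation is a clipped Gaussian with mean well below the
#' soil/vegetation boundary at 5 (default mean 2, sd 1.5) and soil well
#' above it (mean 30, sd 8). Vegetation height follows a scaled Beta over
#' `(0, canopy_height]`; soil height is folded-Gaussian ground roughness.
#' When `event$dew` is `TRUE`, water on the leaves shifts the vegetation
#' intensity distribution upward by `dew_shift` so part of the canopy
#' crosses the boundary and the expected red-reflectance GC drops below its
#' dry-canopy value.
#'
#' @param true_gc True ground cover in (0, 1).
#' @param canopy_height Canopy height in metres (> 0).
#' @param event Sampling event (needs `solar_radiation`, `dew`).
#' @param n_points Number of returns (>= 1).
#' @param seed Integer seed.
#' @param config LiDAR section of [default_config()].
#' @param along_range,cross_range Scanned extent in metres.
#' @return Tibble (along_track, cross_track, z, intensity) of class
#'   `lidar_scan`; intensities lie in \[0, 255\], z >= 0.
#' @export
#' @examples
#' ev <- make_event_schedule()[1, ]
#' scan <- simulate_lidar_scan(0.6, 0.2, ev, n_points = 500, seed = 1)
#' range(scan$intensity)
simulate_lidar_scan <- function(true_gc, canopy_height, event, n_points,
                                seed, config = default_config()$lidar,
                                along_range = c(0, 6),
                                cross_range = c(-config$cross_halfwidth,
                                                config$cross_halfwidth)) {
  check_scalar_number(seed, "seed")
  withr::with_seed(seed, {
    lidar_scan_core(true_gc, canopy_height, event, n_points, config,
                    along_range, cross_range)
  })
}

lidar_scan_core <- function(true_gc, canopy_height, event, n_points, config,
                            along_range, cross_range) {
  check_gc_fraction(true_gc)
  check_scalar_number(canopy_height, "canopy_height")
  if (canopy_height <= 0) abort_domain("`canopy_height` must be > 0")
  event <- as_event(event)
  if (n_points < 1) abort_domain("`n_points` must be >= 1")

  n <- as.integer(n_points)
  veg_mean <- config$veg_int_mean + if (isTRUE(event$dew)) config$dew_shift else 0
  veg <- runif(n) < true_gc
  nv <- sum(veg)
  intensity <- numeric(n)
  intensity[veg] <- rnorm(nv, veg_mean, config$veg_int_sd)
  intensity[!veg] <- rnorm(n - nv, config$soil_int_mean, config$soil_int_sd)
  z <- numeric(n)
  z[veg] <- canopy_height * rbeta(nv, config$height_shape1, config$height_shape2)
  z[!veg] <- abs(rnorm(n - nv, 0, config$ground_sd))
  scan <- tibble::new_tibble(
    list(
      along_track = runif(n, along_range[1], along_range[2]),
      cross_track = runif(n, cross_range[1], cross_range[2]),
      z = z,
      intensity = clip(intensity, 0, 255)
    ),
    nrow = n, class = "lidar_scan"
  )
  scan
}

#' Simulate an active-NDVI reading stream
#'
#' Readings are spaced `travel_speed / rate` metres apart across the region
#' (10 Hz at 1 m/s gives one reading per 0.1 m, i.e. 50 readings over a 5 m
#' region). Each reading is
#' `ndvi_soil + (ndvi_veg - ndvi_soil) * true_gc + noise`, clipped to the
#' instrument range \[0, 0.99\]. Being an active sensor, the generator
#' ignores `solar_radiation` and `dew` by construction.
#'
#' @param true_gc True ground cover in \[0, 1\] (the closed interval: bare
#'   soil and full cover are valid for this sensor).
#' @param event Sampling event (accepted for interface symmetry; unused).
#' @param travel_speed Platform speed, m/s (> 0).
#' @param rate Sampling rate, Hz (> 0).
#' @param region_length Region length, m.
#' @param seed Integer seed.
#' @param config NDVI section of [default_config()].
#' @return Tibble (position, ndvi) of class `ndvi_stream`.
#' @export
#' @examples
#' ev <- make_event_schedule()[1, ]
#' s <- simulate_ndvi_stream(0.5, ev, travel_speed = 1, rate = 10,
#'                           region_length = 5, seed = 1)
#' nrow(s)  # 50
simulate_ndvi_stream <- function(true_gc, event, travel_speed = 1, rate = 10,
                                 region_length = 5, seed,
                                 config = default_config()$ndvi) {
  check_scalar_number(seed, "seed")
  withr::with_seed(seed, {
    ndvi_stream_core(true_gc, event, travel_speed, rate, region_length, config)
  })
}

ndvi_stream_core <- function(true_gc, event, travel_speed, rate,
                             region_length, config) {
  check_scalar_number(true_gc, "true_gc")
  if (true_gc < 0 || true_gc > 1) {
    abort_domain("`true_gc` must lie in [0, 1]")
  }
  as_event(event)  # validated but deliberately unused: active sensor
  if (travel_speed <= 0) abort_domain("`travel_speed` must be > 0")
  if (rate <= 0) abort_domain("`rate` must be > 0")

  spacing <- travel_speed / rate
  position <- seq(0, region_length - spacing / 2, by = spacing)
  level <- config$ndvi_soil + (config$ndvi_veg - config$ndvi_soil) * true_gc
  ndvi <- clip(level + rnorm(length(position), 0, config$noise_sd), 0, 0.99)
  tibble::new_tibble(list(position = position, ndvi = ndvi),
                     nrow = length(position), class = "ndvi_stream")
}

#' Render the full sensor bundle for one plot at one sampling event
#'
#' Produces the three data streams a traverse of one plot yields: RGB images
#' triggered every `image_spacing` metres starting at a seeded random phase
#' (the trigger window extends half a path width beyond each plot end, so a
#' 6 m plot yields 6-7 trigger positions), a LiDAR scan covering the plot
#' extent, and an NDVI stream along the plot. The bundle's seed is derived
#' deterministically from `(master_seed, plot, event_id)` via
#' [derive_seed()], so any single bundle is reproducible in isolation.
#'
#' @param plot Plot identifier (must exist in `design`).
#' @param event_id Event identifier (must exist in `schedule`).
#' @param design,truth Outputs of [simulate_trial()].
#' @param schedule Output of [make_event_schedule()].
#' @param config Full configuration ([default_config()]).
#' @param master_seed Master integer seed.
#' @return List of class `sensor_bundle`: `plot`, `event_id`,
#'   `image_positions`, `images`, `scan`, `ndvi`.
#' @export
render_bundle <- function(plot, event_id, design, truth, schedule,
                          config = default_config(), master_seed) {
  if (!plot %in% design$plot) {
    abort_design(sprintf("plot %s is not in the trial design", plot))
  }
  if (!event_id %in% schedule$event_id) {
    rlang::abort(sprintf("event %s is not in the schedule", event_id),
                 class = "gc_unknown_event")
  }
  event <- as_event(schedule[schedule$event_id == event_id, c("solar_radiation", "dew")])
  tr <- truth[truth$plot == plot, ]
  plot_length <- attr(design, "plot_length")
  half_path <- attr(design, "path_width") / 2

  withr::with_seed(derive_seed(master_seed, plot, event_id), {
    phase <- runif(1)
    image_positions <- seq(-half_path + phase * config$rgb$image_spacing,
                           plot_length + half_path - 1e-9,
                           by = config$rgb$image_spacing)
    images <- rgb_images_core(
      tr$true_gc, event, n_images = length(image_positions),
      image_size = c(config$rgb$image_height, config$rgb$image_width),
      config = config$rgb
    )
    scan <- lidar_scan_core(
      tr$true_gc, tr$canopy_height, event, n_points = config$lidar$n_points,
      config = config$lidar, along_range = c(0, plot_length),
      cross_range = c(-config$lidar$cross_halfwidth, config$lidar$cross_halfwidth)
    )
    ndvi <- ndvi_stream_core(
      tr$true_gc, event, travel_speed = config$ndvi$speed,
      rate = config$ndvi$rate, region_length = plot_length,
      config = config$ndvi
    )
    structure(
      list(plot = plot, event_id = event_id, image_positions = image_positions,
           images = images, scan = scan, ndvi = ndvi),
      class = "sensor_bundle"
    )
  })
}
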