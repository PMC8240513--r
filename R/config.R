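#' Default simulation and estimation configuration
#'
#' Nested list of every tunable parameter in the pipeline. The trial section
#' matches the study conditions the analyses assume (192 plots, 99 genotypes
#' with replication averaging ~1.9, 6 m plots of seven rows at 0.25 m,
#' 0.4 m paths). Effect variances are on the logit scale and give a mean GC
#' near 0.45 with plot-level repeatability near 0.7 under good conditions.
#' Sensor sections control the rendered data streams; see the methods
#' vignette for the rationale behind each default.
#'
#' @return A named list with sections `trial`, `schedule`, `rgb`, `lidar`,
#'   `ndvi` and `estimator`.
#' @export
#' @examples
#' cfg <- default_config()
#' names(cfg)
#' cfg$trial$n_plots
default_config <- function() {
  list(
    trial = list(
      n_plots = 192L,
      n_genotypes = 99L,
      n_field_rows = 8L,
      n_field_cols = 24L,
      plot_length = 6.0,
      n_rows_per_plot = 7L,
      row_spacing = 0.25,
      path_width = 0.4,
      mu = -0.2,               # logit scale; plogis(-0.2) ~ 0.45 mean GC
      sigma2_g = 0.12,
      sigma2_row = 0.02,
      sigma2_col = 0.02,
      sigma2_eps = 0.10,
      height_base = 0.05,      # m; canopy height = base + slope * true_gc
      height_slope = 0.25
    ),
    schedule = list(
      # 12:00-18:00 day one, 07:00-12:00 the next morning
      clock_labels = c(
        "12:00 01-Aug", "13:00 01-Aug", "14:00 01-Aug", "15:00 01-Aug",
        "16:00 01-Aug", "17:00 01-Aug", "18:00 01-Aug",
        "07:00 02-Aug", "08:00 02-Aug", "09:00 02-Aug", "10:00 02-Aug",
        "11:00 02-Aug", "12:00 02-Aug"
      ),
      # effective light during each traverse, MJ m-2 h-1 (see vignette for
      # why the early-morning values sit above the hourly-mean radiation)
      solar_radiation = c(2.0, 2.1, 2.0, 1.7, 1.2, 0.6, 0.1,
                          0.3, 0.6, 0.9, 1.3, 1.8, 2.0),
      dew_events = c(8L, 9L),  # 07:00 and 08:00 the second morning
      dew_light_max = 0.6      # dew only plausible at low light
    ),
    rgb = list(
      image_height = 40L,
      image_width = 56L,
      veg_rgb = c(60, 120, 50),   # green-dominant canopy base colour
      soil_rgb = c(120, 90, 60),  # red-dominant soil base colour
      ambient = 30,               # sensor offset so darkness is not all-black
      noise_sd = 10,              # per-pixel channel noise, 8-bit units
      cast_sd = 2,                # per-image green-channel colour cast
      rad_full = 1.0,             # radiation giving full exposure
      image_spacing = 1.0         # camera trigger interval, m
    ),
    lidar = list(
      n_points = 2000L,
      veg_int_mean = 2, veg_int_sd = 1.5,    # dry canopy reflectance
      soil_int_mean = 30, soil_int_sd = 8,   # soil reflectance
      dew_shift = 6,        # upward shift of vegetation intensity under dew
      ground_sd = 0.02,     # m, uneven-ground roughness
      height_shape1 = 2, height_shape2 = 2,  # Beta shape of canopy returns
      cross_halfwidth = 1.0                  # m, scan swath half width
    ),
    ndvi = list(
      rate = 10,        # Hz
      speed = 1.0,      # m s-1 platform speed
      ndvi_soil = 0.15,
      ndvi_veg = 0.85,
      noise_sd = 0.02
    ),
    estimator = list(
      vi_threshold = 0,
      rr_threshold = 5,
      ht_threshold = 0.10,
      end_buffer = 0.5,
      exclude_outer_rows = TRUE
    )
  )
}

#' Load a configuration file
#'
#' Reads a YAML configuration and merges it over [default_config()], so a
#' file need only state the values it overrides.
#'
#' @param path Path to a YAML file (possibly nested under the same section
#'   names as [default_config()]).
#' @return A full configuration list.
#' @export
load_config <- function(path) {
  user <- yaml::read_yaml(path)
  merge_config(default_config(), user)
}

merge_config <- function(base, user) {
  if (is.null(user)) return(base)
  stopifnot(is.list(user))
  utils::modifyList(base, user)
}

validate_estimator_config <- function(cfg) {
  if (cfg$ht_threshold <= 0) abort_domain("`ht_threshold` must be > 0")
  if (cfg$rr_threshold <= 0 || cfg$rr_threshold >= 255) {
    abort_domain("`rr_threshold` must lie in (0, 255)")
  }
  if (cfg$end_buffer < 0) abort_domain("`end_buffer` must be >= 0")
  invisible(cfg)
}
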