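# File-format interfaces: PNG images, CSV/PLY point clouds, CSV streams.

#' Write and read RGB plot images as PNG
#'
#' Images are named `plot{P}_event{E}_img{K}.png`; values are stored 8-bit.
#'
#' @param images List of `rgb_image` arrays (0-255).
#' @param dir Output directory (created if absent).
#' @param plot,event Identifiers used in the file names.
#' @return Character vector of file paths, invisibly.
#' @export
write_plot_images <- function(images, dir, plot, event) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- purrr::imap_chr(images, function(img, k) {
    path <- file.path(dir, sprintf("plot%s_event%s_img%d.png", plot, event, k))
    png::writePNG(img / 255, path)
    path
  })
  invisible(paths)
}

#' @rdname write_plot_images
#' @param path A PNG file path.
#' @export
read_rgb_png <- function(path) {
  arr <- png::readPNG(path)
  if (length(dim(arr)) == 2L) arr <- array(arr, dim = c(dim(arr), 1L))
  if (dim(arr)[3] < 3L) abort_domain("PNG must have at least 3 channels")
  out <- round(arr[, , 1:3, drop = FALSE] * 255)
  class(out) <- c("rgb_image", class(out))
  out
}

#' Point-cloud I/O (CSV and ASCII PLY)
#'
#' CSV uses columns `x,y,z,intensity` (x = along-track, y = cross-track,
#' metres). PLY is the ASCII variant with float properties
#' `x y z intensity`.
#'
#' @param scan A `lidar_scan`.
#' @param path Output file path; format chosen by extension (.csv or .ply).
#' @return `path` invisibly (writer); a `lidar_scan` (reader).
#' @export
write_point_cloud <- function(scan, path) {
  df <- data.frame(x = scan$along_track, y = scan$cross_track,
                   z = scan$z, intensity = scan$intensity)
  if (grepl("\\.ply$", path, ignore.case = TRUE)) {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(c(
      "ply", "format ascii 1.0",
      sprintf("element vertex %d", nrow(df)),
      "property float x", "property float y", "property float z",
      "property float intensity", "end_header"
    ), con)
    utils::write.table(format(df, digits = 9, trim = TRUE, scientific = FALSE),
                       con, row.names = FALSE, col.names = FALSE,
                       quote = FALSE)
  } else {
    write.csv(df, path, row.names = FALSE)
  }
  invisible(path)
}

#' @rdname write_point_cloud
#' @export
read_point_cloud <- function(path) {
  if (grepl("\\.ply$", path, ignore.case = TRUE)) {
    lines <- readLines(path)
    if (lines[1] != "ply") abort_domain("not a PLY file")
    header_end <- match("end_header", lines)
    if (is.na(header_end)) abort_domain("PLY header has no end_header")
    props <- sub("^property \\S+ ", "", grep("^property ", lines, value = TRUE))
    body <- lines[seq(header_end + 1L, length(lines))]
    body <- body[nzchar(body)]
    df <- utils::read.table(text = body, col.names = props)
  } else {
    df <- read.csv(path)
  }
  need <- c("x", "y", "z", "intensity")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    abort_domain(paste("point cloud missing columns:", paste(miss, collapse = ", ")))
  }
  scan <- tibble::tibble(along_track = df$x, cross_track = df$y,
                         z = df$z, intensity = df$intensity)
  if (any(scan$intensity < 0 | scan$intensity > 255)) {
    abort_domain("intensities must lie in [0, 255]")
  }
  class(scan) <- c("lidar_scan", class(scan))
  scan
}

#' NDVI stream I/O (CSV with columns position, ndvi)
#'
#' @param stream An `ndvi_stream`.
#' @param path CSV file path.
#' @return `path` invisibly (writer); an `ndvi_stream` (reader).
#' @export
write_ndvi_stream <- function(stream, path) {
  write.csv(data.frame(position = stream$position, ndvi = stream$ndvi),
            path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_ndvi_stream
#' @export
read_ndvi_stream <- function(path) {
  df <- read.csv(path)
  if (!all(c("position", "ndvi") %in% names(df))) {
    abort_domain("NDVI stream needs columns `position` and `ndvi`")
  }
  if (any(df$ndvi < 0 | df$ndvi > 0.99)) {
    abort_domain("NDVI values must lie in [0, 0.99]")
  }
  stream <- tibble::tibble(position = df$position, ndvi = df$ndvi)
  class(stream) <- c("ndvi_stream", class(stream))
  stream
}

#' Trial-design I/O
#'
#' The design CSV has one row per plot (`plot,row,col,genotype`); the plot
#' geometry (plot length, rows, spacing, path width) is carried by the
#' configuration and re-attached on read.
#'
#' @param design A `trial_design`.
#' @param path CSV file path.
#' @param trial_config Trial section of [default_config()] supplying the
#'   geometry attributes on read.
#' @return `path` invisibly (writer); a `trial_design` (reader).
#' @export
write_design <- function(design, path) {
  write.csv(as.data.frame(design)[, c("plot", "row", "col", "genotype")],
            path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_design
#' @export
read_design <- function(path, trial_config = default_config()$trial) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("plot", "row", "col", "genotype")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    abort_domain(paste("design missing columns:", paste(miss, collapse = ", ")))
  }
  design <- tibble::as_tibble(df[, need])
  attr(design, "plot_length") <- trial_config$plot_length
  attr(design, "n_rows_per_plot") <- trial_config$n_rows_per_plot
  attr(design, "row_spacing") <- trial_config$row_spacing
  attr(design, "path_width") <- trial_config$path_width
  attr(design, "nrep") <- nrow(design) / length(unique(design$genotype))
  class(design) <- c("trial_design", class(design))
  design
}

#' Estimate a GC table from on-disk sensor files
#'
#' File-based front end to the estimators, for data produced outside the
#' simulator. Images live in one directory named
#' `plot{P}_event{E}_img{K}.png` and are assumed to fall inside the
#' sampling region (positions are not stored in PNG files); the point cloud
#' is a long CSV with columns `plot,event,x,y,z,intensity`; the NDVI file a
#' long CSV with columns `plot,event,position,ndvi`. Clouds and streams are
#' segmented to each plot's sampling region before estimation.
#'
#' @param images_dir Directory of PNG images (or `NULL`).
#' @param cloud_file Long-format point-cloud CSV (or `NULL`).
#' @param ndvi_file Long-format NDVI CSV (or `NULL`).
#' @param design A `trial_design` (or path to a design CSV).
#' @param config Estimator section of [default_config()].
#' @return A `gc_table` covering every (plot, event) seen in the inputs;
#'   methods without data for a plot-event are flagged missing.
#' @export
estimate_from_files <- function(images_dir = NULL, cloud_file = NULL,
                                ndvi_file = NULL, design,
                                config = default_config()$estimator) {
  if (is.character(design)) design <- read_design(design)

  img_index <- NULL
  if (!is.null(images_dir)) {
    files <- list.files(images_dir, pattern = "^plot.+_event.+_img\\d+\\.png$")
    if (length(files)) {
      m <- regmatches(files, regexec("^plot(.+)_event(.+)_img(\\d+)\\.png$", files))
      img_index <- tibble::tibble(
        file = file.path(images_dir, files),
        plot = as.integer(vapply(m, `[`, "", 2)),
        event_id = as.integer(vapply(m, `[`, "", 3))
      )
    }
  }
  cloud <- if (!is.null(cloud_file)) read.csv(cloud_file) else NULL
  ndvi <- if (!is.null(ndvi_file)) read.csv(ndvi_file) else NULL

  keys <- unique(rbind(
    if (!is.null(img_index)) img_index[, c("plot", "event_id")],
    if (!is.null(cloud)) tibble::tibble(plot = cloud$plot, event_id = cloud$event),
    if (!is.null(ndvi)) tibble::tibble(plot = ndvi$plot, event_id = ndvi$event)
  ))
  if (is.null(keys) || nrow(keys) == 0) abort_missing("no sensor data found")

  rows <- purrr::pmap(keys, function(plot, event_id) {
    region <- sampling_region(design, plot, config)

    rgb_val <- NA_real_; n_img <- 0L
    if (!is.null(img_index)) {
      sel <- img_index[img_index$plot == plot & img_index$event_id == event_id, ]
      if (nrow(sel)) {
        rgb_val <- gc_rgb_plot(purrr::map(sel$file, read_rgb_png), config)
        n_img <- nrow(sel)
      }
    }

    rr_val <- NA_real_; ht_val <- NA_real_; n_pts <- 0L
    if (!is.null(cloud)) {
      sel <- cloud[cloud$plot == plot & cloud$event == event_id, ]
      if (nrow(sel)) {
        scan <- tibble::tibble(along_track = sel$x, cross_track = sel$y,
                               z = sel$z, intensity = sel$intensity)
        scan <- clip_scan(scan, region)
        if (nrow(scan)) {
          rr_val <- gc_lidar_rr(scan, config)
          ht_val <- gc_lidar_ht(suppressWarnings(normalize_heights(scan)), config)
          n_pts <- nrow(scan)
        }
      }
    }

    ndvi_val <- NA_real_; n_ndvi <- 0L
    if (!is.null(ndvi)) {
      sel <- ndvi[ndvi$plot == plot & ndvi$event == event_id, ]
      if (nrow(sel)) {
        idx <- assign_to_plot(sel$position, region)
        if (length(idx)) {
          ndvi_val <- mean(sel$ndvi[idx])
          n_ndvi <- length(idx)
        }
      }
    }

    tibble::tibble(plot = plot, event_id = event_id, method = gc_methods(),
                   value = c(ndvi_val, rgb_val, rr_val, ht_val),
                   n_samples = c(n_ndvi, n_img, n_pts, n_pts))
  })
  as_gc_table(dplyr::bind_rows(rows))
}

#' Read a GC table CSV
#'
#' @param path CSV with columns `plot,event_id,method,value,n_samples`.
#' @return A `gc_table`.
#' @export
read_gc_table <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("plot", "event_id", "method", "value", "n_samples")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    abort_domain(paste("GC table missing columns:", paste(miss, collapse = ", ")))
  }
  as_gc_table(tibble::as_tibble(df[, need]))
}
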