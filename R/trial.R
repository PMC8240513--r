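#' Simulate a partial-replicate field trial with known ground truth
#'
#' Generates a trial design (plot grid and genotype assignment) and the
#' latent per-plot ground truth that drives every simulated sensor. Each
#' genotype is sown on one or two plots so that mean replication equals
#' `n_plots / n_genotypes` (~1.94 at the default 192/99 scale). True ground
#' cover is a logit-normal combination of genotype, field-row, field-column
#' and residual plot effects:
#' \deqn{GC = \mathrm{logit}^{-1}(\mu + g + r + c + \epsilon)}
#' which keeps GC strictly inside (0, 1) and makes the variance components
#' interpretable on the link scale. Canopy height increases linearly with
#' true GC (taller, more vigorous canopies cover more ground).
#'
#' @param config Trial section of [default_config()] (or a compatible list).
#' @param seed Integer seed; output is bit-reproducible for a fixed seed.
#' @return A list with elements
#'   * `design`: tibble (plot, row, col, genotype) with geometry attributes
#'     (`plot_length`, `n_rows_per_plot`, `row_spacing`, `path_width`,
#'     `nrep`), class `trial_design`;
#'   * `truth`: tibble (plot, genotype, genotype_effect, row_effect,
#'     col_effect, residual_effect, true_gc, canopy_height), class
#'     `ground_truth`.
#' @export
#' @examples
#' tr <- simulate_trial(default_config()$trial, seed = 1)
#' nrow(tr$design)
#' range(tr$truth$true_gc)
simulate_trial <- function(config = default_config()$trial, seed) {
  check_scalar_number(seed, "seed")
  n_plots <- as.integer(config$n_plots)
  n_geno <- as.integer(config$n_genotypes)
  if (n_geno > n_plots) {
    abort_design("more genotypes than plots: every genotype needs >= 1 plot")
  }
  if (n_plots > 2L * n_geno) {
    abort_design("n_plots > 2 * n_genotypes: partial replication caps each genotype at 2 plots")
  }
  if (config$n_field_rows * config$n_field_cols < n_plots) {
    abort_design("field grid (n_field_rows x n_field_cols) too small for n_plots")
  }

  withr::with_seed(seed, {
    geno_labels <- sprintf("g%03d", seq_len(n_geno))
    n_dup <- n_plots - n_geno
    duplicated_geno <- if (n_dup > 0) sample(geno_labels, n_dup) else character(0)
    pool <- sample(c(geno_labels, duplicated_geno))

    plot <- seq_len(n_plots)
    row <- ((plot - 1L) %% config$n_field_rows) + 1L
    col <- ((plot - 1L) %/% config$n_field_rows) + 1L

    design <- tibble::tibble(plot = plot, row = row, col = col, genotype = pool)
    attr(design, "plot_length") <- config$plot_length
    attr(design, "n_rows_per_plot") <- config$n_rows_per_plot
    attr(design, "row_spacing") <- config$row_spacing
    attr(design, "path_width") <- config$path_width
    attr(design, "nrep") <- n_plots / n_geno
    class(design) <- c("trial_design", class(design))

    g_eff <- stats::setNames(rnorm(n_geno, 0, sqrt(config$sigma2_g)), geno_labels)
    r_eff <- rnorm(config$n_field_rows, 0, sqrt(config$sigma2_row))
    c_eff <- rnorm(config$n_field_cols, 0, sqrt(config$sigma2_col))
    e_eff <- rnorm(n_plots, 0, sqrt(config$sigma2_eps))

    eta <- config$mu + unname(g_eff[design$genotype]) + r_eff[row] +
      c_eff[col] + e_eff
    true_gc <- plogis(eta)
    truth <- tibble::tibble(
      plot = plot,
      genotype = design$genotype,
      genotype_effect = unname(g_eff[design$genotype]),
      row_effect = r_eff[row],
      col_effect = c_eff[col],
      residual_effect = e_eff,
      true_gc = true_gc,
      canopy_height = config$height_base + config$height_slope * true_gc
    )
    class(truth) <- c("ground_truth", class(truth))

    list(design = design, truth = truth)
  })
}

#' Build the diurnal sampling-event schedule
#'
#' Thirteen hourly sampling events — seven on the first afternoon
#' (12:00-18:00) and six the following morning (07:00-12:00) — each with an
#' effective light level and a dew flag. Dew is only permitted at low light
#' (`dew_light_max`), mirroring its formation overnight and persistence in
#' the early morning.
#'
#' @param config Schedule section of [default_config()].
#' @return Tibble (event_id, clock_label, solar_radiation, dew), class
#'   `event_schedule`.
#' @export
#' @examples
#' sched <- make_event_schedule()
#' nrow(sched)
make_event_schedule <- function(config = default_config()$schedule) {
  n <- length(config$clock_labels)
  if (length(config$solar_radiation) != n) {
    abort_domain("`solar_radiation` must have one value per clock label")
  }
  if (any(config$solar_radiation < 0)) {
    abort_domain("`solar_radiation` must be >= 0")
  }
  dew <- seq_len(n) %in% as.integer(config$dew_events %||% integer(0))
  bad <- dew & config$solar_radiation > config$dew_light_max
  if (any(bad)) {
    abort_domain(sprintf(
      "dew flagged at high light (events %s): dew requires solar_radiation <= %g",
      paste(which(bad), collapse = ", "), config$dew_light_max
    ))
  }
  sched <- tibble::tibble(
    event_id = seq_len(n),
    clock_label = config$clock_labels,
    solar_radiation = as.numeric(config$solar_radiation),
    dew = dew
  )
  class(sched) <- c("event_schedule", class(sched))
  sched
}

#' Read an hourly meteorological schedule from CSV
#'
#' Expects columns `event,time,date,t_air,t_dew,rh,radiation,dew_flag`; the
#' packaged fixture at [met_schedule_path()] transcribes the hourly weather
#' table for the two 2017 sampling campaigns at the Yanco field site.
#'
#' @param path CSV file path.
#' @return Tibble of class `event_schedule` with the met columns retained.
#' @export
#' @examples
#' met <- read_met_schedule(met_schedule_path())
#' met[met$clock_label == "07:00 02-Aug-2017", c("solar_radiation", "dew")]
read_met_schedule <- function(path) {
  raw <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("event", "time", "date", "t_air", "t_dew", "rh", "radiation", "dew_flag")
  miss <- setdiff(need, names(raw))
  if (length(miss)) {
    abort_domain(paste("met schedule missing columns:", paste(miss, collapse = ", ")))
  }
  sched <- tibble::tibble(
    event_id = seq_len(nrow(raw)),
    campaign = raw$event,
    clock_label = paste(raw$time, raw$date),
    solar_radiation = as.numeric(raw$radiation),
    dew = as.logical(raw$dew_flag),
    t_air = as.numeric(raw$t_air),
    t_dew = as.numeric(raw$t_dew),
    rh = as.numeric(raw$rh)
  )
  class(sched) <- c("event_schedule", class(sched))
  sched
}

#' Path to the packaged meteorological fixture
#' @return File path of the installed CSV fixture.
#' @export
met_schedule_path <- function() {
  system.file("extdata", "met_schedule_2017.csv", package = "groundcover",
              mustWork = TRUE)
}

#' Simulate per-plot observations from the observation-scale mixed model
#'
#' Draws plot values directly from
#' `value = mu + genotype + row + col + residual` with independent zero-mean
#' Gaussian effects, given an existing [simulate_trial()] design. This is
#' the generator used in variance-component recovery studies, where the
#' truth must live on the same scale the model is fitted on.
#'
#' @param design A `trial_design`.
#' @param sigma2_g,sigma2_row,sigma2_col,sigma2_eps True variances.
#' @param mu Grand mean (default 0).
#' @param seed Integer seed.
#' @return Tibble (plot, value).
#' @export
simulate_plot_values <- function(design, sigma2_g, sigma2_row, sigma2_col,
                                 sigma2_eps, mu = 0, seed) {
  check_scalar_number(seed, "seed")
  withr::with_seed(seed, {
    geno <- sort(unique(design$genotype))
    g <- stats::setNames(rnorm(length(geno), 0, sqrt(sigma2_g)), geno)
    rr <- stats::setNames(rnorm(length(unique(design$row)), 0, sqrt(sigma2_row)),
                          sort(unique(design$row)))
    cc <- stats::setNames(rnorm(length(unique(design$col)), 0, sqrt(sigma2_col)),
                          sort(unique(design$col)))
    e <- rnorm(nrow(design), 0, sqrt(sigma2_eps))
    tibble::tibble(
      plot = design$plot,
      value = mu + unname(g[design$genotype]) +
        unname(rr[as.character(design$row)]) +
        unname(cc[as.character(design$col)]) + e
    )
  })
}
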