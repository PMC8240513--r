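#' Per-event summary of GC estimates
#'
#' Mean and sample standard deviation over plots for each (event, method),
#' with a count of flagged-missing plots.
#'
#' @param table A `gc_table`.
#' @return Tibble (event_id, method, mean, sd, n, n_missing).
#' @export
summarize_events <- function(table) {
  if (nrow(table) == 0) abort_missing("empty GC table")
  dplyr::summarise(
    dplyr::group_by(tibble::as_tibble(table), .data$event_id, .data$method),
    mean = mean(.data$value, na.rm = TRUE),
    sd = sd(.data$value, na.rm = TRUE),
    n = sum(!is.na(.data$value)),
    n_missing = sum(is.na(.data$value)),
    .groups = "drop"
  )
}

#' Pair event-mean GC with solar radiation
#'
#' Joins the per-event method means to the schedule's light levels, one row
#' per (event, method), for GC-versus-light summaries.
#'
#' @param table A `gc_table`.
#' @param schedule An `event_schedule` covering every event in `table`.
#' @return Tibble (event_id, clock_label, method, solar_radiation, mean_gc).
#' @export
gc_vs_light <- function(table, schedule) {
  summary <- summarize_events(table)
  missing <- setdiff(unique(summary$event_id), schedule$event_id)
  if (length(missing)) {
    rlang::abort(sprintf("events missing from schedule: %s",
                         paste(missing, collapse = ", ")),
                 class = "gc_join_error")
  }
  out <- dplyr::inner_join(
    summary,
    dplyr::select(tibble::as_tibble(schedule),
                  "event_id", "clock_label", "solar_radiation"),
    by = "event_id"
  )
  dplyr::arrange(
    dplyr::select(out, "event_id", "clock_label", "method",
                  "solar_radiation", mean_gc = "mean"),
    .data$method, .data$event_id
  )
}

#' Run the full diurnal experiment
#'
#' End-to-end orchestration: simulate the trial and schedule, render and
#' estimate every plot-by-event sensor bundle, fit the per-event variance
#' components, and assemble the reliability products — event summaries,
#' GC-versus-light pairs, per-method intraclass correlation matrices,
#' per-event phenotypic correlation matrices, and the repeatability table.
#' Deterministic end to end for a fixed `master_seed`; when `out_dir` is
#' given, all products are written as CSV and two identically seeded runs
#' produce byte-identical files.
#'
#' Bundles are rendered and estimated one at a time so the raw sensor
#' streams never need to be held in memory together.
#'
#' @param config Full configuration ([default_config()]).
#' @param master_seed Master integer seed.
#' @param out_dir Optional output directory (created if absent). On any
#'   stage failure partially written outputs are removed.
#' @param fit_methods Methods to fit variance components for (default all
#'   four); phenotypic correlations need at least two.
#' @param verbose Log one line per stage with counts.
#' @return List of class `experiment_report`: `design`, `truth`,
#'   `schedule`, `gc_table`, `event_summary`, `gc_vs_light`, `icc`,
#'   `phenotypic`, `variance_components`, `repeatability_table`,
#'   `provenance`.
#' @export
run_experiment <- function(config = default_config(), master_seed,
                           out_dir = NULL, fit_methods = gc_methods(),
                           verbose = TRUE) {
  check_scalar_number(master_seed, "master_seed")
  stopifnot(all(fit_methods %in% gc_methods()))
  say <- function(...) if (verbose) message(sprintf(...))

  stage <- "simulate"
  result <- tryCatch({
    trial <- simulate_trial(config$trial, seed = derive_seed(master_seed, salt = 99))
    schedule <- make_event_schedule(config$schedule)
    say("simulate: %d plots, %d genotypes, %d events",
        nrow(trial$design), length(unique(trial$design$genotype)), nrow(schedule))

    stage <- "estimate"
    rows <- vector("list", nrow(trial$design) * nrow(schedule))
    k <- 0L
    for (ev in schedule$event_id) {
      for (p in trial$design$plot) {
        b <- render_bundle(p, ev, trial$design, trial$truth, schedule,
                           config, master_seed)
        k <- k + 1L
        rows[[k]] <- estimate_bundle(b, trial$design, config$estimator)
      }
    }
    gc_table <- as_gc_table(dplyr::bind_rows(rows))
    say("estimate: %d rows (%d plot-events x 4 methods), %d missing values",
        nrow(gc_table), k, sum(is.na(gc_table$value)))

    stage <- "summarize"
    event_summary <- summarize_events(gc_table)
    light <- gc_vs_light(gc_table, schedule)

    stage <- "stats"
    icc <- purrr::map(stats::setNames(gc_methods(), gc_methods()),
                      ~ icc_matrix(gc_table, .x))
    vcs <- list()
    rep_rows <- list()
    for (m in fit_methods) {
      for (ev in schedule$event_id) {
        sub <- gc_table[gc_table$method == m & gc_table$event_id == ev, ]
        vc <- fit_random_effects(
          tibble::tibble(plot = sub$plot, value = sub$value), trial$design
        )
        vcs[[paste(m, ev, sep = ".")]] <- vc
        rep_rows[[paste(m, ev, sep = ".")]] <- tibble::tibble(
          event_id = ev, method = m,
          sigma2_g = vc$sigma2_g, sigma2_row = vc$sigma2_row,
          sigma2_col = vc$sigma2_col, sigma2_eps = vc$sigma2_eps,
          nrep = vc$nrep, rho = suppressWarnings(repeatability(vc))
        )
      }
    }
    repeatability_table <- dplyr::bind_rows(rep_rows)
    say("stats: %d variance-component fits", length(vcs))

    phenotypic <- if (length(fit_methods) >= 2) {
      purrr::map(stats::setNames(schedule$event_id, schedule$event_id), function(ev) {
        means <- purrr::map(stats::setNames(fit_methods, fit_methods),
                            ~ genotype_means(vcs[[paste(.x, ev, sep = ".")]]))
        phenotypic_corr_matrix(means)
      })
    } else list()

    report <- structure(
      list(design = trial$design, truth = trial$truth, schedule = schedule,
           gc_table = gc_table, event_summary = event_summary,
           gc_vs_light = light, icc = icc, phenotypic = phenotypic,
           variance_components = vcs,
           repeatability_table = repeatability_table,
           provenance = list(master_seed = master_seed, config = config,
                             fit_methods = fit_methods,
                             package_version = as.character(utils::packageVersion("groundcover")))),
      class = "experiment_report"
    )

    if (!is.null(out_dir)) {
      stage <- "write"
      write_report(report, out_dir)
      say("write: outputs in %s", out_dir)
    }
    report
  }, error = function(e) {
    if (!is.null(out_dir) && dir.exists(out_dir)) {
      unlink(file.path(out_dir, report_files()), force = TRUE)
    }
    rlang::abort(sprintf("stage '%s' failed: %s", stage, conditionMessage(e)),
                 class = "gc_stage_error", parent = e)
  })
  result
}

report_files <- function() {
  c("design.csv", "ground_truth.csv", "schedule.csv", "gc_table.csv",
    "event_summary.csv", "gc_vs_light.csv", "repeatability.csv",
    "genotype_means.csv", "provenance.yml",
    paste0("icc_", tolower(gc_methods()), "_r.csv"),
    paste0("icc_", tolower(gc_methods()), "_stars.csv"),
    "phenotypic_r.csv", "phenotypic_stars.csv")
}

write_matrix_csv <- function(m, path) {
  df <- data.frame(id = rownames(m), m, check.names = FALSE)
  write.csv(df, path, row.names = FALSE)
}

#' Write an experiment report to CSV files
#'
#' @param report An `experiment_report`.
#' @param out_dir Output directory (created if absent).
#' @return `out_dir`, invisibly.
#' @export
write_report <- function(report, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  w <- function(df, file) write.csv(df, file.path(out_dir, file), row.names = FALSE)
  w(as.data.frame(report$design), "design.csv")
  w(as.data.frame(report$truth), "ground_truth.csv")
  w(as.data.frame(report$schedule), "schedule.csv")
  w(as.data.frame(report$gc_table), "gc_table.csv")
  w(as.data.frame(report$event_summary), "event_summary.csv")
  w(as.data.frame(report$gc_vs_light), "gc_vs_light.csv")
  w(as.data.frame(report$repeatability_table), "repeatability.csv")

  gm <- purrr::imap(report$variance_components, function(vc, key) {
    parts <- strsplit(key, ".", fixed = TRUE)[[1]]
    tibble::tibble(method = parts[1], event_id = as.integer(parts[2]),
                   genotype = names(vc$blups),
                   mean = unname(genotype_means(vc)))
  })
  w(dplyr::bind_rows(gm), "genotype_means.csv")

  for (m in names(report$icc)) {
    write_matrix_csv(report$icc[[m]]$r,
                     file.path(out_dir, paste0("icc_", tolower(m), "_r.csv")))
    write_matrix_csv(report$icc[[m]]$stars,
                     file.path(out_dir, paste0("icc_", tolower(m), "_stars.csv")))
  }
  if (length(report$phenotypic)) {
    ph_r <- purrr::imap(report$phenotypic, function(mat, ev) {
      df <- as.data.frame(mat$r)
      df <- cbind(event_id = ev, method = rownames(mat$r), df)
      df
    })
    ph_s <- purrr::imap(report$phenotypic, function(mat, ev) {
      df <- as.data.frame(mat$stars)
      cbind(event_id = ev, method = rownames(mat$stars), df)
    })
    write.csv(do.call(rbind, ph_r), file.path(out_dir, "phenotypic_r.csv"),
              row.names = FALSE)
    write.csv(do.call(rbind, ph_s), file.path(out_dir, "phenotypic_stars.csv"),
              row.names = FALSE)
  }
  prov <- report$provenance
  yaml::write_yaml(prov, file.path(out_dir, "provenance.yml"))
  invisible(out_dir)
}
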