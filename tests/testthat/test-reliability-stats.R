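# Variance components, repeatability, correlations.

test_that("fit_random_effects recovers known variance components on a balanced design", {
  cfg <- default_config()$trial
  cfg$n_plots <- 200L
  cfg$n_genotypes <- 100L # every genotype replicated twice
  cfg$n_field_rows <- 10L
  cfg$n_field_cols <- 20L
  tr <- simulate_trial(cfg, seed = 1)

  est <- sapply(1:50, function(s) {
    vals <- simulate_plot_values(tr$design, sigma2_g = 2, sigma2_row = 0,
                                 sigma2_col = 0, sigma2_eps = 1, seed = s)
    vc <- fit_random_effects(vals, tr$design)
    c(g = vc$sigma2_g, eps = vc$sigma2_eps)
  })
  expect_lt(abs(mean(est["g", ]) / 2 - 1), 0.15)
  expect_lt(abs(mean(est["eps", ]) / 1 - 1), 0.15)
})

test_that("a zero genotypic variance shrinks both the estimate and the BLUPs", {
  tr <- simulate_trial(small_trial_config(), seed = 2)
  fits <- lapply(1:20, function(s) {
    vals <- simulate_plot_values(tr$design, sigma2_g = 0, sigma2_row = 0,
                                 sigma2_col = 0, sigma2_eps = 1, seed = 100 + s)
    fit_random_effects(vals, tr$design)
  })
  expect_lt(median(sapply(fits, `[[`, "sigma2_g")),
            0.05 * median(sapply(fits, `[[`, "sigma2_eps")))
  expect_lt(median(sapply(fits, function(f) max(abs(f$blups)))), 0.1)
})

test_that("the REML fit is location invariant and scale equivariant", {
  tr <- simulate_trial(small_trial_config(), seed = 3)
  vals <- simulate_plot_values(tr$design, 1, 0.1, 0.1, 0.5, seed = 4)
  vc <- fit_random_effects(vals, tr$design)

  shifted <- vals
  shifted$value <- shifted$value + 10
  vc_shift <- fit_random_effects(shifted, tr$design)
  expect_equal(vc_shift$sigma2_g, vc$sigma2_g, tolerance = 1e-5)
  expect_equal(vc_shift$sigma2_eps, vc$sigma2_eps, tolerance = 1e-5)
  expect_equal(vc_shift$mu, vc$mu + 10, tolerance = 1e-5)

  scaled <- vals
  scaled$value <- scaled$value * 3
  vc_scale <- fit_random_effects(scaled, tr$design)
  expect_equal(vc_scale$sigma2_g, 9 * vc$sigma2_g, tolerance = 1e-3)
  expect_equal(vc_scale$sigma2_eps, 9 * vc$sigma2_eps, tolerance = 1e-3)
})

test_that("degenerate and invalid inputs are handled explicitly", {
  tr <- simulate_trial(small_trial_config(), seed = 5)
  const <- tibble::tibble(plot = tr$design$plot, value = 0.5)
  expect_warning(vc <- fit_random_effects(const, tr$design),
                 class = "gc_degenerate_fit")
  expect_equal(vc$sigma2_g, 0)
  expect_equal(vc$sigma2_eps, 0)
  expect_true(all(vc$blups == 0))

  dup <- tibble::tibble(plot = c(1, 1, 2), value = c(0.1, 0.2, 0.3))
  expect_error(fit_random_effects(dup, tr$design), class = "gc_integrity_error")

  one_geno <- tr$design[tr$design$genotype == tr$design$genotype[1], ]
  vals <- tibble::tibble(plot = one_geno$plot, value = seq_len(nrow(one_geno)))
  expect_error(fit_random_effects(vals, one_geno), class = "gc_invalid_design")
})

test_that("the fitted variances maximise an independently coded restricted likelihood", {
  tr <- simulate_trial(small_trial_config(), seed = 6)
  vals <- simulate_plot_values(tr$design, 1.5, 0.2, 0.2, 1, seed = 7)
  vc <- fit_random_effects(vals, tr$design)

  d <- dplyr::inner_join(vals, tr$design, by = "plot")
  at_fit <- oracle_reml_loglik(
    d, c(vc$sigma2_g, vc$sigma2_row, vc$sigma2_col, vc$sigma2_eps)
  )
  # every perturbation of the solution must not improve the criterion
  withr::with_seed(8, {
    for (k in 1:100) {
      s2 <- c(vc$sigma2_g, vc$sigma2_row, vc$sigma2_col, vc$sigma2_eps) *
        exp(rnorm(4, 0, 0.3))
      s2 <- pmax(s2, 1e-8)
      expect_lte(oracle_reml_loglik(d, s2), at_fit + 1e-4)
    }
  })
})

test_that("repeatability follows its closed form and responds monotonically", {
  expect_equal(repeatability(1, 1, 1), 0.5)
  expect_equal(repeatability(0, 1, 2), 0)
  expect_equal(repeatability(2, 1, 2), 0.8)

  grid <- expand.grid(g = c(0.5, 1, 2), e = c(0.5, 1, 2), n = c(1, 1.9, 3))
  rho <- with(grid, mapply(repeatability, g, e, n))
  # increasing in sigma2_g
  for (e in unique(grid$e)) for (n in unique(grid$n)) {
    sub <- rho[grid$e == e & grid$n == n]
    expect_true(all(diff(sub) > 0))
  }
  # decreasing in sigma2_eps, increasing in nrep
  expect_true(all(tapply(rho, paste(grid$g, grid$n),
                         function(x) all(diff(x) < 0))))
  o <- order(grid$g, grid$e, grid$n)
  expect_true(all(tapply(rho[o], paste(grid$g, grid$e)[o],
                         function(x) all(diff(x) > 0))))

  expect_warning(out <- repeatability(0, 0, 2),
                 class = "gc_undefined_repeatability")
  expect_true(is.na(out))
})

test_that("significance stars use the strict threshold ladder", {
  expect_equal(p_stars(c(0.2, 0.04, 0.009, 0.0009, 0.00009)),
               c("", "*", "**", "***", "****"))
  expect_equal(p_stars(0.0001), "***")  # strict: not four stars
  expect_equal(p_stars(0.05), "")
  expect_equal(p_stars(NA), "")
})

test_that("pearson_with_stars matches the closed-form coefficient and flags degeneracy", {
  res <- pearson_with_stars(1:6, 2 * (1:6) + 1)
  expect_equal(res$r, 1)
  expect_equal(res$stars, "****")

  x <- c(1, 2, 3, 4, 5)
  y <- c(2, 1, 4, 3, 6)
  res2 <- pearson_with_stars(x, y)
  expect_equal(res2$r, oracle_pearson_r(x, y))
  expect_equal(res2$n, 5)

  # pairwise-complete deletion
  res3 <- pearson_with_stars(c(x, NA, 7), c(y, 1, NA))
  expect_equal(res3$n, 5)
  expect_equal(res3$r, res2$r)

  flat <- pearson_with_stars(rep(1, 5), 1:5)
  expect_true(is.na(flat$r))
  expect_equal(flat$stars, "")

  expect_error(pearson_with_stars(1:2, 2:3), class = "gc_missing_data")
})

test_that("icc_matrix is symmetric with unit diagonal and detects shared structure", {
  # duplicated event columns: perfect intraclass correlation
  base <- tibble::tibble(plot = 1:20, value = runif(20))
  tab <- dplyr::bind_rows(
    dplyr::mutate(base, event_id = 1, method = "NDVI", n_samples = 50),
    dplyr::mutate(base, event_id = 2, method = "NDVI", n_samples = 50)
  )
  m <- icc_matrix(tab, "NDVI")
  expect_equal(m$r[1, 2], 1)
  expect_equal(diag(m$r), c(`1` = 1, `2` = 1))
  expect_equal(m$r, t(m$r))

  # independently re-randomised plot values: near-zero ICC at 192 plots
  withr::with_seed(10, {
    null_tab <- dplyr::bind_rows(lapply(1:5, function(ev) {
      tibble::tibble(plot = 1:192, event_id = ev, method = "NDVI",
                     value = runif(192), n_samples = 50)
    }))
  })
  null_m <- icc_matrix(null_tab, "NDVI")
  expect_lt(mean(abs(null_m$r[upper.tri(null_m$r)])), 0.15)
})

test_that("a stable sensor yields high ICC across all 13 events", {
  tr <- simulate_trial(default_config()$trial, seed = 11)
  sched <- make_event_schedule()
  tab <- dplyr::bind_rows(lapply(sched$event_id, function(ev) {
    values <- sapply(seq_len(nrow(tr$truth)), function(i) {
      ndvi_plot_mean(simulate_ndvi_stream(
        tr$truth$true_gc[i], sched[ev, ], 1, 10, 5,
        seed = derive_seed(12, i, ev)
      ))
    })
    tibble::tibble(plot = tr$design$plot, event_id = ev, method = "NDVI",
                   value = values, n_samples = 50)
  }))
  m <- icc_matrix(tab, "NDVI")
  expect_true(all(m$r[upper.tri(m$r)] > 0.8))
})

test_that("phenotypic correlations separate shared signal from noise", {
  means_a <- stats::setNames(runif(99), sprintf("g%03d", 1:99))
  means_b <- 2 * means_a + 1
  m <- phenotypic_corr_matrix(list(A = means_a, B = means_b))
  expect_equal(m$r["A", "B"], 1)
  expect_equal(diag(m$r), c(A = 1, B = 1))

  # two methods observing the same truth with independent noise
  tr <- simulate_trial(default_config()$trial, seed = 13)
  obs <- function(noise_seed) {
    withr::with_seed(noise_seed, {
      tibble::tibble(plot = tr$design$plot,
                     value = tr$truth$true_gc + rnorm(nrow(tr$design), 0, 0.03))
    })
  }
  vc1 <- fit_random_effects(obs(1), tr$design)
  vc2 <- fit_random_effects(obs(2), tr$design)
  m2 <- phenotypic_corr_matrix(list(A = genotype_means(vc1),
                                    B = genotype_means(vc2)))
  expect_gt(m2$r["A", "B"], 0.7)

  # one method replaced by pure noise
  noise_means <- withr::with_seed(14, {
    stats::setNames(runif(99), names(genotype_means(vc1)))
  })
  m3 <- phenotypic_corr_matrix(list(A = genotype_means(vc1), N = noise_means))
  expect_lt(abs(m3$r["A", "N"]), 0.25)

  # disagreeing genotype sets are intersected with a warning
  short <- genotype_means(vc2)[1:60]
  expect_warning(phenotypic_corr_matrix(list(A = genotype_means(vc1), B = short)),
                 class = "gc_low_overlap")
})
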