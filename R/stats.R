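#' Fit the per-event random-effects model
#'
#' REML fit of `value = mu + genotype + row + col + residual` with
#' independent Gaussian random effects for genotype, field row and field
#' column, as used to partition variance for each GC method at each
#' sampling time. Spatial trend is represented by the row and column
#' effects. BLUPs of genotype effects are predicted at the REML solution;
#' with the genotype variance estimated at zero they shrink to zero. The
#' fit is deterministic given the data.
#'
#' @param values Tibble with columns `plot` and `value` (one observation
#'   per plot; `NA` values are dropped).
#' @param design A `trial_design` providing genotype, row, col per plot.
#' @return List of class `variance_components`: `sigma2_g`, `sigma2_row`,
#'   `sigma2_col`, `sigma2_eps`, `nrep`, `mu`, `blups` (named vector,
#'   one per genotype present), `n_obs`.
#' @export
#' @examples
#' tr <- simulate_trial(default_config()$trial, seed = 1)
#' vals <- simulate_plot_values(tr$design, 1, 0.05, 0.05, 1, seed = 2)
#' vc <- fit_random_effects(vals, tr$design)
#' repeatability(vc)
fit_random_effects <- function(values, design) {
  d <- dplyr::inner_join(
    dplyr::select(tibble::as_tibble(values), "plot", "value"),
    dplyr::select(tibble::as_tibble(design), "plot", "genotype", "row", "col"),
    by = "plot"
  )
  d <- d[!is.na(d$value), ]
  if (anyDuplicated(d$plot)) abort_integrity("duplicated plot in `values`")
  if (length(unique(d$genotype)) < 2) {
    abort_design("at least 2 genotypes with observations are required")
  }
  nrep <- attr(design, "nrep") %||% (nrow(design) / length(unique(design$genotype)))

  geno_levels <- sort(unique(d$genotype))
  if (sd(d$value) == 0) {
    rlang::warn("all values identical: every variance component is 0",
                class = "gc_degenerate_fit")
    return(new_variance_components(
      0, 0, 0, 0, nrep, mu = d$value[1],
      blups = stats::setNames(rep(0, length(geno_levels)), geno_levels),
      n_obs = nrow(d)
    ))
  }

  d$genotype <- factor(d$genotype)
  d$row <- factor(d$row)
  d$col <- factor(d$col)
  fit <- suppressMessages(lme4::lmer(
    value ~ 1 + (1 | genotype) + (1 | row) + (1 | col),
    data = d, REML = TRUE,
    control = lme4::lmerControl(calc.derivs = FALSE,
                                check.conv.singular = "ignore")
  ))
  vc <- as.data.frame(lme4::VarCorr(fit))
  get_var <- function(grp) vc$vcov[vc$grp == grp]
  re <- lme4::ranef(fit)$genotype
  blups <- stats::setNames(re[["(Intercept)"]], rownames(re))

  new_variance_components(
    sigma2_g = get_var("genotype"),
    sigma2_row = get_var("row"),
    sigma2_col = get_var("col"),
    sigma2_eps = get_var("Residual"),
    nrep = nrep,
    mu = unname(lme4::fixef(fit)[1]),
    blups = blups[geno_levels],
    n_obs = nrow(d)
  )
}

new_variance_components <- function(sigma2_g, sigma2_row, sigma2_col,
                                    sigma2_eps, nrep, mu, blups, n_obs) {
  structure(
    list(sigma2_g = sigma2_g, sigma2_row = sigma2_row, sigma2_col = sigma2_col,
         sigma2_eps = sigma2_eps, nrep = nrep, mu = mu, blups = blups,
         n_obs = n_obs),
    class = "variance_components"
  )
}

#' Genotype means from a fitted model
#'
#' `mu + BLUP`, one value per genotype.
#'
#' @param vc A `variance_components` object.
#' @return Named numeric vector.
#' @export
genotype_means <- function(vc) {
  vc$mu + vc$blups
}

#' Repeatability (broad-sense heritability at plot level)
#'
#' \deqn{\rho = \sigma^2_g / (\sigma^2_g + \sigma^2_\epsilon / n_{rep})}
#' where \eqn{n_{rep}} is the mean number of genotype replicates. Undefined
#' (returns `NA` with a warning) when both variances are zero.
#'
#' @param vc A `variance_components` object, or the genotypic variance
#'   \eqn{\sigma^2_g} when `sigma2_eps` and `nrep` are given.
#' @param sigma2_eps,nrep Residual variance and mean replication (only when
#'   `vc` is numeric).
#' @return Repeatability in \[0, 1\], or `NA`.
#' @export
#' @examples
#' repeatability(1, 1, 1)  # 0.5
#' repeatability(2, 1, 2)  # 0.8
repeatability <- function(vc, sigma2_eps = NULL, nrep = NULL) {
  if (inherits(vc, "variance_components")) {
    sigma2_g <- vc$sigma2_g
    sigma2_eps <- vc$sigma2_eps
    nrep <- vc$nrep
  } else {
    sigma2_g <- vc
  }
  if (sigma2_g < 0 || sigma2_eps < 0) abort_domain("variances must be >= 0")
  if (nrep <= 0) abort_domain("`nrep` must be > 0")
  if (sigma2_g == 0 && sigma2_eps == 0) {
    rlang::warn("repeatability undefined: both variances are zero",
                class = "gc_undefined_repeatability")
    return(NA_real_)
  }
  sigma2_g / (sigma2_g + sigma2_eps / nrep)
}

#' Significance stars for a p-value
#'
#' `"****"` for p < 0.0001, `"***"` for p < 0.001, `"**"` for p < 0.01,
#' `"*"` for p < 0.05, otherwise `""`. Boundaries are strict.
#'
#' @param p A p-value (vectorised; `NA` gives `""`).
#' @return Character vector of stars.
#' @export
p_stars <- function(p) {
  out <- character(length(p))
  out[!is.na(p) & p < 0.05] <- "*"
  out[!is.na(p) & p < 0.01] <- "**"
  out[!is.na(p) & p < 0.001] <- "***"
  out[!is.na(p) & p < 0.0001] <- "****"
  out
}

#' Pearson correlation with significance stars
#'
#' Standard Pearson r on pairwise-complete observations, two-sided p-value
#' from the t transform on n - 2 degrees of freedom, and significance
#' stars. Zero variance in either variable yields an undefined-correlation
#' result (`r = NA`) rather than an error.
#'
#' @param x,y Paired numeric vectors.
#' @return List of class `correlation_result`: `r`, `p`, `n`, `stars`.
#' @export
#' @examples
#' pearson_with_stars(1:10, 2 * (1:10) + 1)
pearson_with_stars <- function(x, y) {
  ok <- stats::complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3) abort_missing("at least 3 complete pairs are required")
  if (sd(x) == 0 || sd(y) == 0) {
    return(structure(list(r = NA_real_, p = NA_real_, n = n, stars = ""),
                     class = "correlation_result"))
  }
  ct <- stats::cor.test(x, y, method = "pearson", alternative = "two.sided")
  structure(
    list(r = unname(ct$estimate), p = ct$p.value, n = n,
         stars = p_stars(ct$p.value)),
    class = "correlation_result"
  )
}

#' Intraclass correlation matrix across sampling events
#'
#' For a single method, the Pearson correlation of per-plot values between
#' every pair of sampling events: a symmetric matrix with unit diagonal.
#' Pairs sharing fewer than 3 plots give a missing cell.
#'
#' @param table A `gc_table`.
#' @param method One of [gc_methods()].
#' @return List of class `correlation_matrix` with matrices `r`, `p`, `n`
#'   and `stars`, dimnames = event ids.
#' @export
icc_matrix <- function(table, method) {
  stopifnot(method %in% table$method)
  sub <- table[table$method == method, c("plot", "event_id", "value")]
  wide <- tidyr::pivot_wider(sub, names_from = "event_id", values_from = "value")
  events <- setdiff(names(wide), "plot")
  if (length(events) < 2) abort_missing("need >= 2 events with this method")
  correlation_matrix_over(
    purrr::map(events, ~ wide[[.x]]), labels = events, kind = "icc"
  )
}

#' Phenotypic correlation matrix between methods
#'
#' Pearson correlations of genotype means (`mu + BLUP`) between GC methods
#' at a single sampling event. Genotype sets are intersected across
#' methods; a warning is raised when the overlap drops below 80%.
#'
#' @param means_by_method Named list of named vectors of genotype means
#'   (e.g. from [genotype_means()]), one per method.
#' @return List of class `correlation_matrix` (matrices `r`, `p`, `n`,
#'   `stars`, dimnames = method names).
#' @export
phenotypic_corr_matrix <- function(means_by_method) {
  if (length(means_by_method) < 2) abort_missing("need >= 2 methods")
  sets <- purrr::map(means_by_method, names)
  common <- Reduce(intersect, sets)
  union_n <- length(Reduce(union, sets))
  if (length(common) < 0.8 * union_n) {
    rlang::warn(sprintf("genotype sets overlap on only %d of %d genotypes",
                        length(common), union_n),
                class = "gc_low_overlap")
  }
  if (length(common) < 3) abort_missing("fewer than 3 shared genotypes")
  correlation_matrix_over(
    purrr::map(means_by_method, ~ unname(.x[common])),
    labels = names(means_by_method), kind = "phenotypic"
  )
}

# Shared construction of a symmetric correlation matrix with stars.
correlation_matrix_over <- function(columns, labels, kind) {
  k <- length(columns)
  r <- matrix(NA_real_, k, k, dimnames = list(labels, labels))
  p <- r
  n <- matrix(NA_integer_, k, k, dimnames = list(labels, labels))
  stars <- matrix("", k, k, dimnames = list(labels, labels))
  for (i in seq_len(k)) {
    r[i, i] <- 1
    n[i, i] <- sum(!is.na(columns[[i]]))
    for (j in seq_len(k)) {
      if (j <= i) next
      ok <- stats::complete.cases(columns[[i]], columns[[j]])
      if (sum(ok) < 3) next
      res <- pearson_with_stars(columns[[i]], columns[[j]])
      r[i, j] <- r[j, i] <- res$r
      p[i, j] <- p[j, i] <- res$p
      n[i, j] <- n[j, i] <- res$n
      stars[i, j] <- stars[j, i] <- res$stars
    }
  }
  structure(list(r = r, p = p, n = n, stars = stars, kind = kind),
            class = "correlation_matrix")
}

#' Mean off-diagonal correlation
#'
#' Convenience summary of a [icc_matrix()] / [phenotypic_corr_matrix()]
#' result: the mean of the off-diagonal correlations (missing cells
#' dropped).
#'
#' @param m A `correlation_matrix`.
#' @return A single number.
#' @export
mean_off_diagonal <- function(m) {
  r <- m$r
  mean(r[upper.tri(r)], na.rm = TRUE)
}
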