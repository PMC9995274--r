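#' Weighted average parental age
#'
#' The age axis of the parental-age model: the average of the paternal and
#' maternal ages at reproduction, weighted by the paternal fraction of
#' germline mutations, `tau = p * father_age + (1 - p) * mother_age`.
#'
#' @param father_age,mother_age ages at reproduction in years (vectorised).
#' @param paternal_fraction weight p in `[0, 1]`.
#' @return Numeric vector of weighted ages in years.
#' @examples
#' weighted_parental_age(10, 6, 0.5)
#' @export
weighted_parental_age <- function(father_age, mother_age,
                                  paternal_fraction = 0.5) {
  check_that(all(!is.na(father_age) & !is.na(mother_age)),
             "parental ages must be known; substitute generation time upstream")
  check_that(all(father_age > 0 & mother_age > 0),
             "parental ages must be positive")
  p <- paternal_fraction
  check_that(all(p >= 0 & p <= 1), "`paternal_fraction` must lie in [0, 1]")
  p * father_age + (1 - p) * mother_age
}

#' Fit the Poisson parental-age model
#'
#' Models the number of de novo mutations in trio i as Poisson with mean
#' \deqn{\lambda_i = (1 - FNR_i) \, 2 C_i \, d_{s(i)} (a + b \tau_i)}
#' where `a` is the mutational contribution at birth (mutations per site
#' already present in gametes of a newborn parent), `b` the additional
#' mutations per site per year of weighted parental age `tau`, and `d_s` a
#' multiplicative species deviation. The identity link (rather than log) is
#' deliberate: the biology is additive — a fixed load at birth plus a linear
#' accumulation with age — with positivity enforced during optimisation.
#'
#' Fitting proceeds in two stages: stage 1 maximises the Poisson likelihood
#' over `(a, b)` with all `d_s = 1`; stage 2 fits each `d_s` by per-species
#' maximum likelihood holding `(a, b)` fixed, which has the closed form
#' `d_s = sum(m_i) / sum(lambda0_i)`. Trios without both parental ages are
#' excluded from fitting.
#'
#' @param observations a tibble with one row per trio: `trio_id`, `species`,
#'   `m` (de novo count), `n_callable`, `fnr`, `father_age`, `mother_age`
#'   (years, may be `NA`), and optionally `paternal_fraction` (defaults to
#'   0.5 when absent).
#' @return An object of class `age_model_fit` with elements `a`, `b`,
#'   `se_a`, `se_b`, `species_deviation` (tibble: `species`, `d_s`,
#'   `n_trios`), `log_lik`, `log_lik_stage1`, `fitted` (per-trio tibble with
#'   `lambda0` and `lambda`), `convergence`. Supports [tidy()], [glance()]
#'   and [autoplot()].
#' @export
fit_age_model <- function(observations) {
  needed <- c("trio_id", "species", "m", "n_callable", "fnr",
              "father_age", "mother_age")
  check_that(all(needed %in% names(observations)),
             paste0("`observations` needs columns: ",
                    paste(needed, collapse = ", ")))
  obs <- observations
  if (!"paternal_fraction" %in% names(obs)) obs$paternal_fraction <- 0.5
  obs$paternal_fraction[is.na(obs$paternal_fraction)] <- 0.5
  obs <- obs[!is.na(obs$father_age) & !is.na(obs$mother_age), , drop = FALSE]
  check_that(nrow(obs) >= 2, "at least two trios with known ages are required")
  obs$tau <- weighted_parental_age(obs$father_age, obs$mother_age,
                                   obs$paternal_fraction)
  check_that(length(unique(obs$tau)) >= 2,
             "all weighted ages are identical; the age slope is unidentifiable")
  obs$exposure <- (1 - obs$fnr) * 2 * obs$n_callable

  fit1 <- fit_ab_poisson(obs$m, obs$exposure, obs$tau)

  # stage 2: per-species multiplicative deviation, closed-form ML
  lambda0 <- obs$exposure * (fit1$a + fit1$b * obs$tau)
  dev <- tibble(species = obs$species, m = obs$m, lambda0 = lambda0) |>
    group_by(.data$species) |>
    summarise(d_s = sum(.data$m) / sum(.data$lambda0), n_trios = n(),
              .groups = "drop")
  lambda <- lambda0 * dev$d_s[match(obs$species, dev$species)]

  loglik <- function(lam) sum(stats::dpois(obs$m, lam, log = TRUE))
  fitted_tbl <- tibble(
    trio_id = obs$trio_id, species = obs$species, m = obs$m,
    tau = obs$tau, exposure = obs$exposure,
    lambda0 = lambda0, lambda = lambda
  )
  structure(
    list(
      a = fit1$a, b = fit1$b, se_a = fit1$se_a, se_b = fit1$se_b,
      species_deviation = dev |> select("species", "d_s", "n_trios"),
      log_lik = loglik(lambda),
      log_lik_stage1 = loglik(lambda0),
      fitted = fitted_tbl,
      convergence = fit1$convergence,
      n_trios = nrow(obs),
      n_excluded = nrow(observations) - nrow(obs)
    ),
    class = "age_model_fit"
  )
}

# Maximum-likelihood fit of m ~ Poisson(exposure * (a + b * tau)), identity
# link with positivity. Parameters are scaled to per-Gb units (x 1e9) so the
# optimiser works near unity.
fit_ab_poisson <- function(m, exposure, tau) {
  scale <- 1e9
  nll <- function(theta) {
    lam <- exposure * (theta[1] + theta[2] * tau) / scale
    if (any(lam <= 0)) return(1e12)
    sum(lam - m * log(lam))
  }
  # moment start: weighted least squares on per-site rates
  rate <- m / exposure * scale
  start <- tryCatch({
    cf <- coef(lm(rate ~ tau, weights = exposure))
    c(max(cf[1], 1e-3), max(cf[2], 1e-4))
  }, error = function(e) c(5, 0.5))
  opt <- optim(start, nll, method = "Nelder-Mead",
               control = list(maxit = 2000, reltol = 1e-12))
  # polish + curvature for standard errors
  opt <- optim(opt$par, nll, method = "Nelder-Mead",
               control = list(maxit = 2000, reltol = 1e-12))
  h <- tryCatch(stats::optimHess(opt$par, nll), error = function(e) NULL)
  se <- c(NA_real_, NA_real_)
  if (!is.null(h)) {
    v <- tryCatch(solve(h), error = function(e) NULL)
    if (!is.null(v) && all(diag(v) > 0)) se <- sqrt(diag(v))
  }
  list(a = opt$par[1] / scale, b = opt$par[2] / scale,
       se_a = se[1] / scale, se_b = se[2] / scale,
       convergence = opt$convergence == 0)
}

#' Variance explained by the fitted age model
#'
#' Coefficient of determination between predicted Poisson means and observed
#' de novo counts, `r2 = 1 - SS_res / SS_tot`, computed on counts (not
#' rates) overall and per group when a grouping column is given.
#'
#' @param fit an [fit_age_model()] object.
#' @param groups optional character vector, one group label per fitted trio
#'   (in the order of `fit$fitted`), e.g. taxonomic class.
#' @return A tibble with `group` ("overall" first), `n`, `r_squared`.
#' @export
predict_counts_r2 <- function(fit, groups = NULL) {
  check_that(inherits(fit, "age_model_fit"), "`fit` must be an age_model_fit")
  f <- fit$fitted
  check_that(nrow(f) >= 3, "at least three observations are required")
  r2 <- function(obs, pred) {
    1 - sum((obs - pred)^2) / sum((obs - mean(obs))^2)
  }
  out <- tibble(group = "overall", n = nrow(f),
                r_squared = r2(f$m, f$lambda))
  if (!is.null(groups)) {
    check_that(length(groups) == nrow(f),
               "`groups` must have one label per fitted trio")
    per <- tibble(group = groups, m = f$m, lambda = f$lambda) |>
      group_by(.data$group) |>
      summarise(n = n(), r_squared = r2(.data$m, .data$lambda),
                .groups = "drop")
    out <- bind_rows(out, per)
  }
  out
}

#' Modelled rates at species generation time
#'
#' Evaluates the fitted age model at each species' generation time:
#' `mu_generation_modelled = d_s * (a + b * G)` and
#' `mu_yearly_modelled = mu_generation_modelled / G`. This corrects for the
#' difference between the ages at which the sampled parents happened to
#' reproduce and the typical generation time of the species. Confidence
#' intervals come from a parametric bootstrap: counts are resampled from the
#' fitted Poisson means and both fitting stages are repeated.
#'
#' @param fit an [fit_age_model()] object.
#' @param species_meta a tibble with `species` and `generation_time` (years).
#' @param boot number of bootstrap replicates (default 1000; reduce for
#'   speed).
#' @param conf confidence level.
#' @param seed integer seed for the bootstrap.
#' @return A tibble per species: `species`, `generation_time`, `d_s`,
#'   `d_flagged` (TRUE when the species had no fitted trios and `d_s = 1`
#'   was assumed), `mu_generation_modelled`, `mu_yearly_modelled`, and
#'   bootstrap bounds `ci_low_gen`, `ci_high_gen`, `ci_low_yearly`,
#'   `ci_high_yearly`.
#' @export
modelled_rates <- function(fit, species_meta, boot = 1000, conf = 0.95,
                           seed = 1) {
  check_that(inherits(fit, "age_model_fit"), "`fit` must be an age_model_fit")
  check_that(all(c("species", "generation_time") %in% names(species_meta)),
             "`species_meta` needs species and generation_time columns")
  meta <- species_meta |> filter(!is.na(.data$generation_time))
  if (nrow(meta) < nrow(species_meta)) {
    warn("species without generation time skipped")
  }
  check_that(all(meta$generation_time > 0), "generation times must be positive")

  dev <- fit$species_deviation
  d_s <- dev$d_s[match(meta$species, dev$species)]
  flagged <- is.na(d_s)
  d_s[flagged] <- 1

  g <- meta$generation_time
  mu_gen <- d_s * (fit$a + fit$b * g)

  # parametric bootstrap over both stages
  f <- fit$fitted
  lo <- (1 - conf) / 2
  boot_gen <- matrix(NA_real_, nrow = boot, ncol = nrow(meta))
  if (boot > 0) {
    set.seed(seed)
    for (r in seq_len(boot)) {
      m_star <- rpois(nrow(f), f$lambda)
      fb <- tryCatch(fit_ab_poisson(m_star, f$exposure, f$tau),
                     error = function(e) NULL)
      if (is.null(fb)) next
      lam0 <- f$exposure * (fb$a + fb$b * f$tau)
      db <- tibble(species = f$species, m = m_star, l0 = lam0) |>
        group_by(.data$species) |>
        summarise(d = sum(.data$m) / sum(.data$l0), .groups = "drop")
      d_star <- db$d[match(meta$species, db$species)]
      d_star[is.na(d_star)] <- 1
      boot_gen[r, ] <- d_star * (fb$a + fb$b * g)
    }
  }
  ci_gen <- apply(boot_gen, 2, quantile, probs = c(lo, 1 - lo), na.rm = TRUE)
  if (boot == 0) ci_gen <- matrix(NA_real_, 2, nrow(meta))

  tibble(
    species = meta$species,
    generation_time = g,
    d_s = d_s,
    d_flagged = flagged,
    mu_generation_modelled = mu_gen,
    mu_yearly_modelled = mu_gen / g,
    ci_low_gen = ci_gen[1, ],
    ci_high_gen = ci_gen[2, ],
    ci_low_yearly = ci_gen[1, ] / g,
    ci_high_yearly = ci_gen[2, ] / g
  )
}

#' @export
print.age_model_fit <- function(x, ...) {
  cat("Poisson parental-age model\n")
  cat(sprintf("  intercept at birth a: %.3e mutations/site\n", x$a))
  cat(sprintf("  age slope b:          %.3e mutations/site/year\n", x$b))
  cat(sprintf("  trios fitted: %d (%d excluded, no ages); species: %d\n",
              x$n_trios, x$n_excluded, nrow(x$species_deviation)))
  cat(sprintf("  log-likelihood: %.2f (stage 1: %.2f)\n",
              x$log_lik, x$log_lik_stage1))
  invisible(x)
}

#' @rdname fit_age_model
#' @param x an `age_model_fit` object.
#' @param ... unused.
#' @export
tidy.age_model_fit <- function(x, ...) {
  tibble(
    term = c("intercept_at_birth", "age_slope"),
    estimate = c(x$a, x$b),
    std.error = c(x$se_a, x$se_b)
  )
}

#' @rdname fit_age_model
#' @export
glance.age_model_fit <- function(x, ...) {
  tibble(
    log_lik = x$log_lik,
    n_trios = x$n_trios,
    n_species = nrow(x$species_deviation),
    r_squared = predict_counts_r2(x)$r_squared[1],
    converged = x$convergence
  )
}

#' @rdname fit_age_model
#' @param object an `age_model_fit` object.
#' @export
autoplot.age_model_fit <- function(object, ...) {
  ggplot2::ggplot(object$fitted,
                  ggplot2::aes(x = .data$lambda, y = .data$m)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey50") +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::labs(x = "predicted mutations per trio",
                  y = "observed mutations per trio",
                  title = "Poisson parental-age model fit") +
    ggplot2::theme_minimal()
}
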