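#' Phylogenetic generalized least squares
#'
#' Regression of one species-level variable on others with error covariance
#' proportional to shared branch lengths under a Brownian-motion model
#' (Pagel's lambda fixed at 1 by default). With a star phylogeny the
#' covariance is proportional to the identity and the fit reduces exactly to
#' ordinary least squares. The r-squared compares the residual quadratic
#' form against an intercept-only GLS fit in the same metric, and the
#' adjusted value is `1 - (1 - r2) (n - 1) / (n - k - 1)`.
#'
#' @param data a data frame with a `species` column matching the tree's tip
#'   labels plus the model variables.
#' @param formula model formula, e.g. `mu ~ generation_time`.
#' @param tree a rooted tree of class `phylo` with branch lengths in time
#'   units; should be ultrametric (checked with a warning, not an error).
#' @param lambda Pagel's lambda scaling of off-diagonal covariances; 1 is
#'   pure Brownian motion, 0 recovers OLS.
#' @return An object of class `pgls_fit` with `coefficients` (tibble: term,
#'   estimate, std.error, statistic, p.value), `r_squared`,
#'   `adj_r_squared`, `sigma2`, `n`, `formula`, `lambda`, `residuals`,
#'   `data`, `tree`. Supports [tidy()], [glance()] and [autoplot()].
#' @export
pgls_fit <- function(data, formula, tree, lambda = 1) {
  check_that(inherits(tree, "phylo"), "`tree` must be an ape phylo object")
  check_that("species" %in% names(data), "`data` needs a species column")
  vars <- all.vars(formula)
  d <- data[stats::complete.cases(data[, c("species", vars)]), , drop = FALSE]
  missing_tips <- setdiff(d$species, tree$tip.label)
  check_that(length(missing_tips) == 0,
             paste0("species missing from the tree: ",
                    paste(missing_tips, collapse = ", ")))
  check_that(nrow(d) >= 4, "at least four species are required for PGLS")
  check_that(anyDuplicated(d$species) == 0, "one row per species is required")

  tree <- ape::keep.tip(tree, d$species)
  depths <- ape::node.depth.edgelength(tree)[seq_along(tree$tip.label)]
  if (diff(range(depths)) > 1e-6 * max(depths)) {
    warn("tree is not ultrametric; proceeding with given branch lengths")
  }
  V <- ape::vcv.phylo(tree)[d$species, d$species]
  if (lambda != 1) {
    V_off <- V * lambda
    diag(V_off) <- diag(V)
    V <- V_off
  }

  X <- stats::model.matrix(formula, data = d)
  y <- stats::model.response(stats::model.frame(formula, data = d))
  n <- nrow(X)
  k <- ncol(X) - 1

  # GLS through the Cholesky whitening transform
  L <- chol(V)
  Xw <- backsolve(L, X, transpose = TRUE)
  yw <- backsolve(L, y, transpose = TRUE)
  XtX <- crossprod(Xw)
  beta <- solve(XtX, crossprod(Xw, yw))
  resid_w <- yw - Xw %*% beta
  rss <- sum(resid_w^2)
  sigma2 <- rss / (n - k - 1)
  vcov_beta <- sigma2 * solve(XtX)
  se <- sqrt(diag(vcov_beta))
  tstat <- drop(beta) / se
  pval <- 2 * stats::pt(abs(tstat), df = n - k - 1, lower.tail = FALSE)

  # null (intercept-only) fit in the same metric
  ones_w <- backsolve(L, rep(1, n), transpose = TRUE)
  mu_gls <- sum(ones_w * yw) / sum(ones_w^2)
  tss <- sum((yw - ones_w * mu_gls)^2)
  r2 <- 1 - rss / tss
  adj_r2 <- 1 - (1 - r2) * (n - 1) / (n - k - 1)

  structure(
    list(
      coefficients = tibble(
        term = colnames(X), estimate = drop(beta), std.error = se,
        statistic = tstat, p.value = pval
      ),
      r_squared = r2, adj_r_squared = adj_r2, sigma2 = sigma2,
      n = n, formula = formula, lambda = lambda,
      residuals = drop(X %*% beta) - y, data = d, tree = tree
    ),
    class = "pgls_fit"
  )
}

#' @export
print.pgls_fit <- function(x, ...) {
  cat("PGLS (Brownian motion, lambda =", x$lambda, "),", x$n, "species\n")
  print(as.data.frame(x$coefficients))
  cat(sprintf("adjusted r-squared = %.3f\n", x$adj_r_squared))
  invisible(x)
}

#' @rdname pgls_fit
#' @param x,object a `pgls_fit` object.
#' @param ... unused.
#' @export
tidy.pgls_fit <- function(x, ...) x$coefficients

#' @rdname pgls_fit
#' @export
glance.pgls_fit <- function(x, ...) {
  slope_p <- if (nrow(x$coefficients) >= 2) x$coefficients$p.value[2]
             else NA_real_
  tibble(r_squared = x$r_squared, adj_r_squared = x$adj_r_squared,
         sigma2 = x$sigma2, n = x$n, p_value = slope_p)
}

#' @rdname pgls_fit
#' @export
autoplot.pgls_fit <- function(object, ...) {
  vars <- all.vars(object$formula)
  check_that(length(vars) == 2, "autoplot supports single-predictor fits")
  cf <- object$coefficients$estimate
  ggplot2::ggplot(object$data,
                  ggplot2::aes(x = .data[[vars[2]]], y = .data[[vars[1]]])) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::geom_abline(intercept = cf[1], slope = cf[2],
                         colour = "steelblue") +
    ggplot2::labs(title = sprintf("PGLS: adjusted r-squared = %.2f",
                                  object$adj_r_squared)) +
    ggplot2::theme_minimal()
}

#' Ordinary least squares with adjusted r-squared
#'
#' Thin wrapper around `lm()` for the non-phylogenetic regressions (for
#' example per-generation rate against weighted parental age across trios).
#'
#' @param data a data frame holding the model variables.
#' @param formula model formula with a single response.
#' @return A one-row tibble: `intercept`, `slope`, `adj_r_squared`,
#'   `p_value` (two-sided, on the slope), `n`.
#' @export
ols_adjusted_r2 <- function(data, formula) {
  vars <- all.vars(formula)
  d <- data[stats::complete.cases(data[, vars]), , drop = FALSE]
  check_that(nrow(d) >= 3, "at least three points are required")
  check_that(length(vars) == 2, "a single predictor is expected")
  check_that(var(d[[vars[2]]]) > 0, "predictor has zero variance")
  m <- lm(formula, data = d)
  s <- summary(m)
  tibble(
    intercept = coef(m)[[1]],
    slope = coef(m)[[2]],
    adj_r_squared = s$adj.r.squared,
    p_value = s$coefficients[2, 4],
    n = nrow(d)
  )
}

#' Time-weighted harmonic mean of an Ne trajectory
#'
#' Computes the harmonic mean effective population size over a time window
#' from a piecewise-constant (PSMC-style) trajectory:
#' `H = (total overlapped time) / integral(dt / Ne(t))`. Segments partially
#' covered by the window are clipped to their overlap.
#'
#' @param traj a tibble with columns `t_start`, `t_end` (years before
#'   present, `t_start < t_end`) and `ne`.
#' @param window_start,window_end window bounds in years before present.
#' @return The harmonic mean Ne (scalar).
#' @examples
#' traj <- tibble::tibble(t_start = c(0, 5e5), t_end = c(5e5, 1e6),
#'                        ne = c(1e4, 2e4))
#' harmonic_mean_ne(traj, 0, 1e6)
#' @export
harmonic_mean_ne <- function(traj, window_start, window_end) {
  check_that(all(c("t_start", "t_end", "ne") %in% names(traj)),
             "`traj` needs t_start, t_end, ne columns")
  check_that(window_start < window_end, "window must have positive length")
  check_that(all(traj$ne > 0), "Ne values must be positive")
  check_that(all(traj$t_end > traj$t_start), "segments must have positive length")
  overlap <- pmin(traj$t_end, window_end) - pmax(traj$t_start, window_start)
  overlap <- pmax(overlap, 0)
  total <- sum(overlap)
  check_that(total > 0, "window does not overlap the trajectory support")
  total / sum(overlap / traj$ne)
}

#' Effective population size from nucleotide diversity
#'
#' Under neutral equilibrium `pi = 4 Ne mu`, so `Ne = pi / (4 mu)`.
#'
#' @param pi nucleotide diversity per site (vectorised).
#' @param mu per-site per-generation mutation rate; must be positive.
#' @return Numeric vector of Ne estimates.
#' @examples
#' ne_from_pi(0.001, 2.5e-8)
#' @export
ne_from_pi <- function(pi, mu) {
  check_that(all(pi >= 0), "`pi` must be non-negative")
  check_that(all(mu > 0), "`mu` must be positive")
  pi / (4 * mu)
}

#' Step plot of one or more Ne trajectories
#'
#' @param traj a tibble with `t_start`, `t_end`, `ne` and optionally
#'   `species`.
#' @return A ggplot object (time before present on a log axis).
#' @export
plot_ne_trajectory <- function(traj) {
  if (!"species" %in% names(traj)) traj$species <- "trajectory"
  d <- traj |>
    group_by(.data$species) |>
    arrange(.data$t_start, .by_group = TRUE) |>
    ungroup()
  ggplot2::ggplot(d) +
    ggplot2::geom_segment(ggplot2::aes(
      x = pmax(.data$t_start, 1), xend = .data$t_end,
      y = .data$ne, yend = .data$ne, colour = .data$species)) +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "years before present", y = "effective population size",
                  colour = NULL) +
    ggplot2::theme_minimal()
}
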