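#' Wilson score interval
#'
#' Closed-form Wilson score confidence interval for a binomial proportion,
#' the interval behind the per-trio and per-species mutation-rate CIs.
#'
#' @param k number of successes (vectorised).
#' @param n number of trials; must be positive.
#' @param conf confidence level, default 0.95.
#' @return A tibble with columns `low` and `high`; always contains `k / n`.
#' @examples
#' wilson_interval(50, 100)
#' @export
wilson_interval <- function(k, n, conf = 0.95) {
  check_that(all(n > 0), "`n` must be positive")
  check_that(all(k >= 0 & k <= n), "`k` must lie in [0, n]")
  check_that(conf > 0 && conf < 1, "`conf` must be in (0, 1)")
  z <- qnorm(1 - (1 - conf) / 2)
  p <- k / n
  denom <- n + z^2
  centre <- (k + z^2 / 2) / denom
  half <- z * sqrt(k * (n - k) / n + z^2 / 4) / denom
  tibble(low = pmax(0, centre - half), high = pmin(1, centre + half))
}

#' Count callable sites in a trio table
#'
#' A site is callable when a de novo mutation occurring there could have been
#' detected: both parents are confidently homozygous reference and all three
#' individuals pass the depth window and the genotype-quality floor. The
#' site-annotation filters are deliberately not applied here; they act only
#' on polymorphic sites and enter through the false-negative-rate correction
#' instead.
#'
#' @inheritParams call_dnms
#' @param m_depth mean trio depth; computed from the table when `NULL`.
#' @return A one-row tibble: `n_callable`, `n_total`, and exclusion counts
#'   `n_not_homref_parents`, `n_fail_dp`, `n_fail_gq` (a site may appear in
#'   several exclusion counts).
#' @export
count_callable_sites <- function(sites, cfg = filter_config(),
                                 m_depth = NULL) {
  check_that(is.data.frame(sites) && nrow(sites) > 0,
             "an all-sites table (or a callable mask) is required to count callable sites")
  check_site_table(sites)
  if (is.null(m_depth)) {
    m_depth <- mean(c(mean(sites$dp_father, na.rm = TRUE),
                      mean(sites$dp_mother, na.rm = TRUE),
                      mean(sites$dp_offspring, na.rm = TRUE)))
  }
  parents_homref <- sites$gt_father == "HomRef" & sites$gt_mother == "HomRef"
  dp_ok <- function(dp) !is.na(dp) & dp > cfg$dp_low_factor * m_depth &
    dp < cfg$dp_high_factor * m_depth
  gq_ok <- function(gq) !is.na(gq) & gq >= cfg$gq_min
  dp_pass <- dp_ok(sites$dp_father) & dp_ok(sites$dp_mother) &
    dp_ok(sites$dp_offspring)
  gq_pass <- gq_ok(sites$gq_father) & gq_ok(sites$gq_mother) &
    gq_ok(sites$gq_offspring)
  callable <- parents_homref & dp_pass & gq_pass
  tibble(
    n_callable = sum(callable),
    n_total = nrow(sites),
    n_not_homref_parents = sum(!parents_homref),
    n_fail_dp = sum(!dp_pass),
    n_fail_gq = sum(!gq_pass)
  )
}

#' Estimate the false-negative rate of the filter cascade
#'
#' The callable-genome definition accounts for the Mendelian, depth and
#' genotype-quality filters, but the site-annotation filters and the allelic
#' balance filter act only on polymorphic sites and would remove a fraction
#' of true de novo mutations. That fraction is estimated in two parts:
#'
#' * `f_site` — analytic, from the null distributions of the annotations
#'   that follow a known distribution: MQRankSum and ReadPosRankSum are
#'   standard normal at well-behaved sites, so their tail mass outside the
#'   configured bounds is normal tail probability; FS is a phred-scaled
#'   uniform p-value, so `P(FS > fs_max) = 10^(-fs_max / 10)`. The three
#'   losses combine multiplicatively assuming independence.
#' * `f_ab` — empirical, the fraction of transmitted heterozygote sites (one
#'   parent HomRef, the other HomAlt, offspring Het) whose offspring
#'   alternative-allele fraction falls outside the allelic-balance window;
#'   these sites mirror a true heterozygote's read sampling.
#'
#' @inheritParams call_dnms
#' @param f_ab optional externally supplied allelic-balance loss fraction;
#'   required when the table holds no transmitted-het sites.
#' @return A one-row tibble: `f_site`, `f_ab`, `fnr_total`
#'   (`1 - (1 - f_site) * (1 - f_ab)`), `n_het_sites`.
#' @export
estimate_fnr <- function(sites, cfg = filter_config(), f_ab = NULL) {
  f_site <- fnr_site_component(cfg)
  n_het <- 0L
  if (is.null(f_ab)) {
    check_that(is.data.frame(sites) && nrow(sites) > 0,
               "a site table is needed to estimate the allelic-balance loss")
    het <- ((sites$gt_father == "HomRef" & sites$gt_mother == "HomAlt") |
              (sites$gt_father == "HomAlt" & sites$gt_mother == "HomRef")) &
      sites$gt_offspring == "Het"
    n_het <- sum(het)
    check_that(n_het > 0,
               "no transmitted heterozygote sites in the table; supply `f_ab` explicitly")
    hs <- sites[het, , drop = FALSE]
    n_inf <- hs$ad_ref_offspring + hs$ad_alt_offspring
    ab <- ifelse(n_inf > 0, hs$ad_alt_offspring / n_inf, NA_real_)
    outside <- is.na(ab) | ab < cfg$ab_min | ab > cfg$ab_max
    f_ab <- mean(outside)
  } else {
    check_that(f_ab >= 0 && f_ab < 1, "`f_ab` must be in [0, 1)")
  }
  tibble(
    f_site = f_site,
    f_ab = f_ab,
    fnr_total = 1 - (1 - f_site) * (1 - f_ab),
    n_het_sites = n_het
  )
}

# analytic site-filter loss under the annotation null distributions
fnr_site_component <- function(cfg = filter_config()) {
  q_fs <- 10^(-cfg$fs_max / 10)
  q_mqrs <- pnorm(cfg$mqrs_min) + pnorm(cfg$mqrs_max, lower.tail = FALSE)
  q_rprs <- pnorm(cfg$rprs_min) + pnorm(cfg$rprs_max, lower.tail = FALSE)
  1 - (1 - q_fs) * (1 - q_mqrs) * (1 - q_rprs)
}

#' Per-generation mutation rate with FNR correction
#'
#' Computes `mu = m / ((1 - fnr) * 2 * C)`: the de novo count divided by the
#' number of callable chromosomes, inflated for the fraction of true
#' mutations the polymorphic-site filters would have removed. The 95%
#' interval is the Wilson score interval on `(m, 2C)` scaled by
#' `1 / (1 - fnr)`.
#'
#' @param m de novo mutation count (vectorised).
#' @param fnr false-negative rate in `[0, 1)`.
#' @param n_callable callable genome size C (sites).
#' @param conf confidence level.
#' @return A tibble: `n_dnm`, `n_callable`, `fnr`, `mu`, `ci_low`, `ci_high`.
#' @examples
#' per_generation_rate(10, 0.05, 2.0e9)
#' @export
per_generation_rate <- function(m, fnr, n_callable, conf = 0.95) {
  check_that(all(m >= 0), "`m` must be non-negative")
  check_that(all(fnr >= 0 & fnr < 1), "`fnr` must lie in [0, 1)")
  check_that(all(n_callable > 0), "`n_callable` must be positive")
  n <- 2 * n_callable
  wi <- wilson_interval(m, n, conf = conf)
  tibble(
    n_dnm = m,
    n_callable = n_callable,
    fnr = fnr,
    mu = m / ((1 - fnr) * n),
    ci_low = wi$low / (1 - fnr),
    ci_high = wi$high / (1 - fnr)
  )
}

#' Naive yearly mutation rate
#'
#' Divides a per-generation rate by the average parental age at reproduction
#' weighted by each parent's mutational contribution, or by the species
#' generation time when parental ages are unknown. This estimator assumes
#' mutations accumulate linearly from conception, with no contribution at
#' birth.
#'
#' @param mu per-generation mutation rate (vectorised).
#' @param father_age,mother_age parental ages at reproduction in years; may
#'   be `NA` when unknown.
#' @param paternal_fraction weight p given to the father's age
#'   (`p = n_paternal / (n_paternal + n_maternal)`).
#' @param generation_time fallback divisor in years for trios without ages.
#' @return A numeric vector of mutations per site per year.
#' @examples
#' naive_yearly_rate(1e-8, 10, 6, paternal_fraction = 0.5)
#' @export
naive_yearly_rate <- function(mu, father_age = NA, mother_age = NA,
                              paternal_fraction = 0.5,
                              generation_time = NA) {
  args <- vctrs_recycle(mu = mu, father_age = father_age,
                        mother_age = mother_age,
                        paternal_fraction = paternal_fraction,
                        generation_time = generation_time)
  have_ages <- !is.na(args$father_age) & !is.na(args$mother_age)
  check_that(all(have_ages | !is.na(args$generation_time)),
             "each trio needs either both parental ages or a generation time")
  check_that(all(args$father_age[have_ages] > 0 &
                   args$mother_age[have_ages] > 0),
             "parental ages must be positive")
  check_that(all(is.na(args$generation_time) | args$generation_time > 0),
             "generation time must be positive")
  p <- args$paternal_fraction
  check_that(all(p >= 0 & p <= 1), "`paternal_fraction` must lie in [0, 1]")
  divisor <- ifelse(have_ages,
                    p * args$father_age + (1 - p) * args$mother_age,
                    args$generation_time)
  args$mu / divisor
}

# recycle scalar arguments against the longest one
vctrs_recycle <- function(...) {
  args <- list(...)
  n <- max(vapply(args, length, integer(1)))
  lapply(args, function(x) {
    if (length(x) == n) x else rep(x, length.out = n)
  })
}

#' Species-level mutation rates from per-trio estimates
#'
#' The species rate is the mean of its trio rates; the species confidence
#' interval is a Wilson interval on the pooled counts `(sum m, sum 2C)`
#' scaled by one minus the callable-weighted mean FNR.
#'
#' @param trios a tibble with columns `species`, `n_dnm`, `n_callable`,
#'   `fnr`, `mu` (as returned by [per_generation_rate()] joined with trio
#'   metadata).
#' @param conf confidence level.
#' @return A tibble with one row per species: `species`, `n_trios`, `mu`,
#'   `ci_low`, `ci_high`, pooled counts.
#' @export
species_rates <- function(trios, conf = 0.95) {
  check_that(all(c("species", "n_dnm", "n_callable", "fnr", "mu") %in%
                   names(trios)),
             "`trios` needs species, n_dnm, n_callable, fnr, mu columns")
  trios |>
    group_by(.data$species) |>
    summarise(
      n_trios = n(),
      mu_species = mean(.data$mu),
      m_pooled = sum(.data$n_dnm),
      n_pooled = 2 * sum(.data$n_callable),
      fnr_pooled = sum(.data$fnr * .data$n_callable) / sum(.data$n_callable),
      .groups = "drop"
    ) |>
    mutate(
      ci_low = wilson_interval(.data$m_pooled, .data$n_pooled, conf)$low /
        (1 - .data$fnr_pooled),
      ci_high = wilson_interval(.data$m_pooled, .data$n_pooled, conf)$high /
        (1 - .data$fnr_pooled)
    ) |>
    rename(mu = "mu_species")
}
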