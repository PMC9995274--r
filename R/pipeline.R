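#' Per-trio mutation rates from site tables
#'
#' Convenience pipeline over a set of trio site tables: calls de novo
#' mutations through the five-filter cascade, counts callable sites,
#' estimates the false-negative rate (analytic site component plus the
#' empirical allelic-balance component from transmitted heterozygotes) and
#' returns the FNR-corrected per-generation rate with its Wilson interval
#' for every trio.
#'
#' @param sites a named list of trio site tables, or a single table with a
#'   `trio_id` column.
#' @param cfg a [filter_config()].
#' @param conf confidence level.
#' @param f_ab optional fixed allelic-balance loss to use for trios without
#'   transmitted-het sites.
#' @return A tibble with one row per trio: `trio_id`, `n_dnm`,
#'   `n_callable`, `f_site`, `f_ab`, `fnr`, `mu`, `ci_low`, `ci_high`.
#' @export
estimate_trio_rates <- function(sites, cfg = filter_config(), conf = 0.95,
                                f_ab = NULL) {
  if (is.data.frame(sites)) {
    check_that("trio_id" %in% names(sites),
               "a single table needs a trio_id column")
    sites <- split(sites, sites$trio_id)
  }
  check_that(length(sites) > 0, "no trios supplied")
  purrr::map_dfr(names(sites), function(id) {
    tbl <- sites[[id]]
    cand <- call_dnms(tbl, cfg, trio_id = id)
    callable <- count_callable_sites(tbl, cfg)
    fnr <- tryCatch(estimate_fnr(tbl, cfg),
                    error = function(e) {
                      check_that(!is.null(f_ab), conditionMessage(e))
                      estimate_fnr(tbl, cfg, f_ab = f_ab)
                    })
    rate <- per_generation_rate(nrow(cand), fnr$fnr_total,
                                callable$n_callable, conf = conf)
    tibble(trio_id = id, n_dnm = nrow(cand),
           n_callable = callable$n_callable,
           f_site = fnr$f_site, f_ab = fnr$f_ab, fnr = fnr$fnr_total,
           mu = rate$mu, ci_low = rate$ci_low, ci_high = rate$ci_high)
  })
}

#' Headline statistics of a trio cohort analysis
#'
#' Computes the summary quantities a cohort analysis reports — mean
#' per-generation rate, male bias per taxonomic class, spectrum statistics,
#' the parental-age regression and Poisson age-model fit, the
#' across-class rate ANOVA and sibling sharing — from curated trio and
#' mutation tables. Every statistic is computed only when the columns it
#' needs are present; otherwise it is reported as not evaluable with the
#' reason, rather than approximated.
#'
#' @param trios per-trio table with (subsets of) columns `trio_id`,
#'   `species`, `class`, `m`, `n_callable`, `fnr`, `father_age`,
#'   `mother_age`, `paternal_fraction`, `n_paternal`, `n_maternal`,
#'   `generation_time`, `family_id`.
#' @param dnms per-mutation table with (subsets of) `ref`, `alt`,
#'   `context`, `group` (taxonomic class), `family_id`, `trio_id`, `chrom`,
#'   `pos`.
#' @return A tibble: `statistic`, `value`, `evaluable`, `reason`.
#' @export
headline_statistics <- function(trios = NULL, dnms = NULL) {
  rows <- list()
  add <- function(name, fn) {
    res <- tryCatch(list(value = fn(), evaluable = TRUE, reason = NA_character_),
                    error = function(e) list(value = NA_real_,
                                             evaluable = FALSE,
                                             reason = conditionMessage(e)))
    rows[[length(rows) + 1]] <<- tibble(statistic = name,
                                        value = as.numeric(res$value),
                                        evaluable = res$evaluable,
                                        reason = res$reason)
  }
  need <- function(tbl, what, cols) {
    check_that(!is.null(tbl), paste0(what, " table not available"))
    miss <- setdiff(cols, names(tbl))
    check_that(length(miss) == 0,
               paste0(what, " table lacks columns: ",
                      paste(miss, collapse = ", ")))
    tbl
  }
  trio_mu <- function() {
    t <- need(trios, "trio", c("m", "n_callable", "fnr"))
    per_generation_rate(t$m, t$fnr, t$n_callable) |>
      mutate(species = t$species, class = t$class)
  }

  add("mu_generation_mean", function() mean(trio_mu()$mu))
  add("alpha_overall", function() {
    t <- need(trios, "trio", c("n_paternal", "n_maternal"))
    alpha_from_counts(tibble(n_paternal = sum(t$n_paternal),
                             n_maternal = sum(t$n_maternal)))$alpha
  })
  for (cl in c("mammals", "birds", "fishes", "reptiles")) {
    local({
      cl_ <- cl
      add(paste0("alpha_", cl_), function() {
        t <- need(trios, "trio", c("n_paternal", "n_maternal", "class"))
        t <- t[t$class == cl_, , drop = FALSE]
        alpha_from_counts(tibble(n_paternal = sum(t$n_paternal),
                                 n_maternal = sum(t$n_maternal)))$alpha
      })
    })
  }
  add("ts_tv_ratio", function() {
    d <- classify_mutations(need(dnms, "mutation", c("ref", "alt")))
    sum(d$is_transition) / sum(!d$is_transition)
  })
  add("strong_to_weak_pct", function() {
    d <- classify_mutations(need(dnms, "mutation", c("ref", "alt")))
    100 * mean(d$is_strong_to_weak)
  })
  add("cpg_share_of_sw_pct", function() {
    d <- classify_mutations(need(dnms, "mutation", c("ref", "alt", "context")))
    sw <- d[d$is_strong_to_weak & !is.na(d$is_cpg), , drop = FALSE]
    check_that(nrow(sw) > 0, "no strong-to-weak mutations with known context")
    100 * mean(sw$is_cpg)
  })
  add("spectrum_chi2", function() {
    d <- classify_mutations(need(dnms, "mutation", c("ref", "alt", "group")))
    spec <- build_spectrum_table(d, group = "group")
    chi_square_test(spec)$statistic
  })
  add("ols_mu_age_adj_r2", function() {
    t <- need(trios, "trio", c("m", "n_callable", "fnr", "father_age",
                               "mother_age"))
    mu <- per_generation_rate(t$m, t$fnr, t$n_callable)$mu
    p <- if ("paternal_fraction" %in% names(t)) t$paternal_fraction else 0.5
    ok <- !is.na(t$father_age) & !is.na(t$mother_age)
    d <- tibble(mu = mu[ok],
                tau = weighted_parental_age(t$father_age[ok],
                                            t$mother_age[ok],
                                            p[ok]))
    ols_adjusted_r2(d, mu ~ tau)$adj_r_squared
  })
  add("age_model_intercept", function() {
    t <- need(trios, "trio", c("trio_id", "species", "m", "n_callable",
                               "fnr", "father_age", "mother_age"))
    fit_age_model(t)$a
  })
  add("age_model_slope", function() {
    t <- need(trios, "trio", c("trio_id", "species", "m", "n_callable",
                               "fnr", "father_age", "mother_age"))
    fit_age_model(t)$b
  })
  add("age_model_r2", function() {
    t <- need(trios, "trio", c("trio_id", "species", "m", "n_callable",
                               "fnr", "father_age", "mother_age"))
    predict_counts_r2(fit_age_model(t))$r_squared[1]
  })
  add("class_anova_f", function() {
    tm <- trio_mu()
    sp <- tm |> group_by(.data$species) |>
      summarise(mu = mean(.data$mu), group = .data$class[1], .groups = "drop")
    class_anova(sp)$f_statistic
  })
  add("sibling_shared_pct", function() {
    d <- need(dnms, "mutation", c("family_id", "trio_id", "chrom", "pos",
                                  "alt"))
    100 * sibling_sharing(d)$shared_fraction
  })
  bind_rows(rows)
}
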