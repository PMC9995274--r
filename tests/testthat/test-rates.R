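test_that("wilson_interval matches the score interval and its boundaries", {
  # cross-check against the independent prop.test score interval (no
  # continuity correction), which implements the same construction
  for (kn in list(c(50, 100), c(3, 20), c(97, 100), c(1, 400))) {
    got <- wilson_interval(kn[1], kn[2])
    ref <- stats::prop.test(kn[1], kn[2], correct = FALSE)$conf.int
    expect_equal(got$low, ref[1], tolerance = 1e-8)
    expect_equal(got$high, ref[2], tolerance = 1e-8)
  }
  expect_equal(wilson_interval(50, 100)$low, 0.4038, tolerance = 1e-4)
  expect_equal(wilson_interval(50, 100)$high, 0.5962, tolerance = 1e-4)
  expect_equal(wilson_interval(0, 100)$low, 0)
  expect_equal(wilson_interval(100, 100)$high, 1)
  expect_error(wilson_interval(1, 0), "positive")
})

test_that("wilson_interval has near-nominal coverage under binomial sampling", {
  set.seed(1203)
  p <- 0.3; n <- 100; reps <- 2000
  k <- rbinom(reps, n, p)
  ci <- wilson_interval(k, n)
  coverage <- mean(ci$low <= p & p <= ci$high)
  expect_gt(coverage, 0.93)
  expect_lt(coverage, 0.97)
})

test_that("callable-site counting matches a hand-built pass pattern", {
  cfg <- filter_config()
  # 10 sites; rows 8, 9, 10 fail (parent Het, low DP, low GQ); rest pass
  rows <- list(
    make_site(gt_offspring = "HomRef", alt = NA, pos = 0),
    make_site(gt_offspring = "HomRef", alt = NA, pos = 1),
    make_site(pos = 2),                                   # candidate, callable
    make_site(gt_offspring = "HomAlt", pos = 3),          # MV but callable
    make_site(gt_offspring = "HomRef", alt = NA, pos = 4,
              qd = 0.5),                                  # bad annotation: still callable
    make_site(gt_offspring = "HomRef", alt = NA, pos = 5),
    make_site(gt_offspring = "Missing", pos = 6),         # GT missing but DP/GQ fine
    make_site(gt_father = "Het", pos = 7),                # parent not HomRef
    make_site(gt_offspring = "HomRef", alt = NA, pos = 8,
              dp = c(60, 60, 10)),                        # depth fail
    make_site(gt_offspring = "HomRef", alt = NA, pos = 9,
              gq = c(10, 70, 70))                         # quality fail
  )
  tbl <- dplyr::bind_rows(rows)
  got <- count_callable_sites(tbl, cfg, m_depth = 60)
  expect_equal(got$n_callable, 7)
  expect_equal(got$n_total, 10)
  expect_equal(got$n_not_homref_parents, 1)
  expect_error(count_callable_sites(tbl[0, ], cfg), "all-sites")
})

test_that("callable counting edge cases: all nominal, all low quality", {
  base <- make_site(gt_offspring = "HomRef", alt = NA)
  tbl <- dplyr::bind_rows(lapply(0:19, function(p) {
    s <- base; s$pos <- p; s
  }))
  expect_equal(count_callable_sites(tbl, filter_config(), 60)$n_callable, 20)
  tbl$gq_offspring <- 10
  expect_equal(count_callable_sites(tbl, filter_config(), 60)$n_callable, 0)
})

test_that("analytic FNR components equal independent normal-CDF calculations", {
  cfg <- filter_config()
  q_mqrs <- pnorm(-2) + (1 - pnorm(4))
  q_rprs <- 2 * pnorm(-3)
  expect_equal(q_mqrs, 0.02278, tolerance = 1e-4)
  expect_equal(q_rprs, 0.00270, tolerance = 1e-4)
  f_site <- estimate_fnr(make_site(), cfg, f_ab = 0)$f_site
  expect_equal(f_site, 1 - (1 - 0.01) * (1 - q_mqrs) * (1 - q_rprs),
               tolerance = 1e-10)
})

test_that("allelic-balance FNR component is the outside fraction of transmitted hets", {
  cfg <- filter_config()
  # 10 transmitted-het sites, 3 with AB outside [0.3, 0.7]
  mk_het <- function(pos, ad) make_site(gt_father = "HomAlt", pos = pos,
                                        ad_offspring = ad)
  tbl <- dplyr::bind_rows(c(
    lapply(0:6, function(p) mk_het(p, c(30, 30))),
    lapply(7:9, function(p) mk_het(p, c(55, 5)))
  ))
  got <- estimate_fnr(tbl, cfg)
  expect_equal(got$f_ab, 0.3)
  expect_equal(got$n_het_sites, 10)
  expect_equal(got$fnr_total, 1 - (1 - got$f_site) * (1 - 0.3))
  # no het sites and no fallback -> refuse
  expect_error(estimate_fnr(make_site(), cfg), "transmitted")
})

test_that("per-generation rate arithmetic and FNR scaling", {
  got <- per_generation_rate(10, 0.05, 2.0e9)
  expect_equal(got$mu, 10 / (0.95 * 4e9), tolerance = 1e-9)
  expect_equal(got$mu, 2.6316e-9, tolerance = 1e-4)
  expect_true(got$ci_low <= got$mu && got$mu <= got$ci_high)

  zero <- per_generation_rate(0, 0.1, 1e9)
  expect_equal(zero$mu, 0)
  expect_equal(zero$ci_low, 0)

  # halving the retained fraction doubles the rate
  expect_equal(per_generation_rate(7, 0.5, 1e9)$mu,
               2 * per_generation_rate(7, 0, 1e9)$mu)
  # scale equivariance in (m, C)
  expect_equal(per_generation_rate(5, 0.1, 1e8)$mu,
               per_generation_rate(50, 0.1, 1e9)$mu)
  expect_error(per_generation_rate(1, 1.0, 1e9), "fnr")
  expect_error(per_generation_rate(1, 0.1, 0), "callable")
})

test_that("naive yearly rate uses weighted ages or generation time", {
  expect_equal(naive_yearly_rate(1e-8, 10, 6, 0.5), 1.25e-9)
  expect_equal(naive_yearly_rate(1e-8, generation_time = 5), 2e-9)
  expect_equal(naive_yearly_rate(1e-8, 10, 6, 1), 1e-9)
  expect_error(naive_yearly_rate(1e-8), "generation time")
})

test_that("species rates pool trio counts with a Wilson interval", {
  trios <- tibble::tibble(
    species = c("a", "a", "b"),
    n_dnm = c(10, 20, 5),
    n_callable = c(1e9, 1e9, 2e9),
    fnr = c(0.05, 0.05, 0.05)
  )
  trios$mu <- per_generation_rate(trios$n_dnm, trios$fnr, trios$n_callable)$mu
  got <- species_rates(trios)
  expect_equal(nrow(got), 2)
  a <- got[got$species == "a", ]
  expect_equal(a$mu, mean(trios$mu[1:2]))
  ref <- wilson_interval(30, 4e9)
  expect_equal(a$ci_low, ref$low / 0.95, tolerance = 1e-10)
  expect_true(a$ci_low <= a$mu && a$mu <= a$ci_high)
})

test_that("per-trio CIs from the full pipeline cover the generating rate", {
  # moderate-rate check at desk scale: planted truth is recovered within
  # the Wilson interval for most simulated trios
  covered <- 0; n_rep <- 12
  for (s in seq_len(n_rep)) {
    cfg <- sim_config(n_sites = 30000, mu_true = 5e-4, het_site_rate = 2e-3,
                      error_site_rate = 1e-4, seed = 300 + s)
    tr <- simulate_trio(cfg, "t")
    est <- estimate_trio_rates(list(t = tr$sites))
    if (est$ci_low <= 5e-4 && 5e-4 <= est$ci_high) covered <- covered + 1
  }
  expect_gte(covered, 10)
})
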