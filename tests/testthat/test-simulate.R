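test_that("a zero mutation rate plants nothing and invalid configs are refused", {
  cfg <- sim_config(n_sites = 5000, mu_true = 0, error_site_rate = 0, seed = 1)
  tr <- simulate_trio(cfg, "t0")
  expect_equal(nrow(tr$truth), 0)
  expect_true(all(tr$sites$gt_offspring == "HomRef" |
                    tr$sites$gt_offspring == "Het"))
  expect_error(sim_config(n_sites = 0), "n_sites")
  expect_error(sim_config(paternal_fraction_true = 1.2), "paternal_fraction")
  expect_warning(simulate_trio(sim_config(n_sites = 1000, mu_true = 1e-8),
                               "tw"),
                 "expected planted")
})

test_that("identical configs give byte-identical site tables", {
  cfg <- sim_config(n_sites = 5000, mu_true = 1e-4, error_site_rate = 1e-3,
                    seed = 17)
  a <- simulate_trio(cfg, "same")
  b <- simulate_trio(cfg, "same")
  expect_identical(a$sites, b$sites)
  expect_identical(a$truth, b$truth)
  # different trio id draws a different realisation
  c <- simulate_trio(cfg, "other")
  expect_false(identical(a$sites$qd, c$sites$qd))
})

test_that("planted counts fall within the exact binomial interval", {
  cfg <- sim_config(n_sites = 1e6, mu_true = 1e-5, seed = 1)
  tr <- simulate_trio(cfg, "big")
  bounds <- qbinom(c(5e-4, 1 - 5e-4), 2e6, 1e-5)
  expect_gte(nrow(tr$truth), bounds[1])
  expect_lte(nrow(tr$truth), bounds[2])
})

test_that("planted counts over replicates are consistent with the binomial law", {
  n <- 5000; mu <- 1e-4; reps <- 200
  cfg <- sim_config(n_sites = n, mu_true = mu, seed = 1001)
  counts <- vapply(seq_len(reps), function(r) {
    nrow(simulate_trio(cfg, paste0("rep", r))$truth)
  }, integer(1))
  # goodness of fit against Binomial(2n, mu), tail bins pooled
  brk <- c(-0.5, 0.5, 1.5, 2.5, Inf)
  obs <- table(cut(counts, brk))
  p <- c(dbinom(0:2, 2 * n, mu), pbinom(2, 2 * n, mu, lower.tail = FALSE))
  gof <- suppressWarnings(chisq.test(as.integer(obs), p = p))
  expect_gt(gof$p.value, 0.01)
})

test_that("the paternal fraction of planted mutations converges to truth", {
  covered <- 0; reps <- 40
  for (r in seq_len(reps)) {
    cfg <- sim_config(n_sites = 50000, mu_true = 5e-4,
                      paternal_fraction_true = 0.7, seed = 2000 + r)
    tr <- simulate_trio(cfg, "p")
    n_pat <- sum(tr$truth$parent_of_origin == "paternal")
    ci <- wilson_interval(n_pat, nrow(tr$truth))
    if (ci$low <= 0.7 && 0.7 <= ci$high) covered <- covered + 1
  }
  expect_gte(covered / reps, 0.85)
})

test_that("error sites carry a detectable failure signature", {
  cfg <- sim_config(n_sites = 20000, mu_true = 0, error_site_rate = 5e-3,
                    het_site_rate = 0, noise = FALSE, seed = 7)
  tr <- simulate_trio(cfg, "err")
  cand <- call_dnms(tr$sites)
  expect_equal(nrow(cand), 0)  # every error site fails at least one filter
})

test_that("cohort bookkeeping: trios, species, tree tips and Ne tables line up", {
  sp <- tiny_species(seed = 3, n_trios_total = 14)
  co <- simulate_cohort(sim_config(species_params = sp, seed = 3))
  expect_equal(nrow(co$trios), 14)
  expect_equal(nrow(co$species), 7)
  expect_equal(sort(co$tree$tip.label), sort(sp$species))
  expect_true(ape::is.ultrametric(co$tree, tol = 1e-6))
  expect_equal(length(unique(co$ne$species)), 7)
  expect_true(all(co$ne$t_end > co$ne$t_start))
  expect_true(all(co$ne$ne > 0))
  # 3 species x 2 trios flavour of the bookkeeping contract
  sp2 <- default_species_params(2, 1, 0, 0, n_trios_total = 6,
                                n_domesticated = 0, seed = 5)
  co2 <- simulate_cohort(sim_config(species_params = sp2, seed = 5))
  expect_equal(nrow(co2$trios), 6)
  expect_equal(length(co2$tree$tip.label), 3)
  bad <- sp2; bad$generation_time[1] <- NA
  expect_error(simulate_cohort(sim_config(species_params = bad)),
               "generation time")
})

test_that("cohorts are deterministic under a fixed seed", {
  cfg <- sim_config(species_params = tiny_species(11), seed = 11)
  a <- simulate_cohort(cfg)
  b <- simulate_cohort(cfg)
  expect_identical(a$trios, b$trios)
  expect_identical(a$dnms, b$dnms)
  expect_identical(ape::write.tree(a$tree), ape::write.tree(b$tree))
})

test_that("count-mode cohorts follow the generating age model", {
  # regression of m / ((1-fnr) 2C) on weighted age recovers the slope
  sp <- default_species_params(30, 10, 5, 5, n_trios_total = 200,
                               n_domesticated = 10, seed = 21)
  co <- simulate_cohort(sim_config(species_params = sp, prob_age_missing = 0,
                                   species_effect_sd = 0, seed = 21))
  t <- co$trios
  rate <- t$m / ((1 - t$fnr) * 2 * t$n_callable)
  tau <- t$paternal_fraction * t$father_age +
    (1 - t$paternal_fraction) * t$mother_age
  sl <- ols_adjusted_r2(tibble::tibble(x = tau, y = rate), y ~ x)
  expect_lt(abs(sl$slope - 0.4e-9) / 0.4e-9, 0.2)
})

test_that("constant Ne trajectories have that harmonic mean everywhere", {
  traj <- tibble::tibble(t_start = c(0, 1e5, 5e5),
                         t_end = c(1e5, 5e5, 2e6), ne = 1e4)
  expect_equal(harmonic_mean_ne(traj, 3e4, 1e6), 1e4)
  expect_equal(harmonic_mean_ne(traj, 0, 2e6), 1e4)
})

test_that("fixtures round-trip losslessly through the package readers", {
  sp <- default_species_params(2, 1, 1, 0, n_trios_total = 6,
                               n_domesticated = 1, seed = 31)
  cfg <- sim_config(n_sites = 1500, mu_true = 5e-4, het_site_rate = 5e-3,
                    error_site_rate = 2e-3, species_params = sp, seed = 31)
  co <- suppressWarnings(simulate_cohort(cfg, mode = "sites"))
  dir <- withr::local_tempdir()
  files <- write_fixtures(co, dir)
  expect_true(all(file.exists(files)))

  id <- names(co$sites)[1]
  back <- read_trio_vcf(file.path(dir, paste0(id, ".vcf")), trio_id = id)
  orig <- co$sites[[id]]
  expect_identical(back$gt_father, orig$gt_father)
  expect_identical(back$gt_mother, orig$gt_mother)
  expect_identical(back$gt_offspring, orig$gt_offspring)
  expect_identical(back$alt, orig$alt)
  expect_equal(back$pos, orig$pos)
  for (col in c("ad_alt_offspring", "dp_father", "gq_offspring")) {
    expect_equal(back[[col]], orig[[col]])
  }
  for (col in c("qd", "fs", "mq", "mq_rank_sum", "read_pos_rank_sum",
                "sor")) {
    expect_equal(back[[col]], orig[[col]], tolerance = 1e-7)
  }

  # VCF header declares the FORMAT and INFO contract
  hdr <- readLines(file.path(dir, paste0(id, ".vcf")), n = 20)
  for (key in c("GT", "AD", "DP", "GQ")) {
    expect_true(any(grepl(paste0("##FORMAT=<ID=", key), hdr)))
  }
  for (key in c("QD", "FS", "MQ", "MQRankSum", "ReadPosRankSum", "SOR")) {
    expect_true(any(grepl(paste0("##INFO=<ID=", key), hdr)))
  }

  # truth table matches the planted mutations
  truth <- readr::read_tsv(file.path(dir, "truth.tsv"),
                           show_col_types = FALSE)
  expect_equal(nrow(truth), nrow(co$truth$planted))
  expect_equal(sum(co$trios$m), nrow(truth))

  tree <- ape::read.tree(file.path(dir, "tree.nwk"))
  expect_setequal(tree$tip.label, co$species$species)
  ne <- read_ne_trajectory(file.path(dir, "ne.tsv"))
  expect_equal(nrow(ne), nrow(co$ne))
  expect_equal(ne$ne, co$ne$ne, tolerance = 1e-9)
})

test_that("shared planted mutations appear in both siblings' site tables", {
  sp <- default_species_params(1, 1, 0, 0, n_trios_total = 4,
                               n_domesticated = 0, seed = 43)
  found <- FALSE
  for (s in c(43, 44, 45, 46, 47, 48)) {
    cfg <- sim_config(n_sites = 3000, mu_true = 5e-4,
                      sibling_share_prob = 0.5, species_params = sp,
                      seed = s)
    co <- suppressWarnings(simulate_cohort(cfg, mode = "sites"))
    fams <- split(co$trios$trio_id, co$trios$family_id)
    fams <- fams[vapply(fams, length, integer(1)) >= 2]
    if (length(fams) == 0) next
    pl <- co$truth$planted
    shared <- pl[pl$shared_with_sibling &
                   pl$trio_id %in% unlist(fams), , drop = FALSE]
    if (nrow(shared) == 0) next
    fam <- fams[[which(vapply(fams, function(f)
      shared$trio_id[1] %in% f, logical(1)))[1]]]
    other <- setdiff(fam, shared$trio_id[1])[1]
    tbl <- co$sites[[other]]
    row <- tbl[match(shared$pos[1], tbl$pos), ]
    if (row$gt_offspring == "Het" && row$alt == shared$alt[1]) found <- TRUE
    if (found) break
  }
  expect_true(found)
})
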