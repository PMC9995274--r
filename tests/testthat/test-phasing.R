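make_evidence <- function(dnm_id, alleles, present, father_gt, mother_gt) {
  tibble::tibble(
    dnm_id = dnm_id,
    read_id = paste0(dnm_id, "_r", seq_along(alleles)),
    linked_pos = 100L,
    linked_allele = alleles,
    dnm_allele_present = present,
    father_gt = father_gt,
    mother_gt = mother_gt,
    offspring_gt = "A/G"
  )
}

test_that("consistent father-diagnostic linkage phases paternal", {
  ev <- make_evidence("d1", c("A", "A", "G"), c(TRUE, TRUE, FALSE),
                      "A/G", "G/G")
  got <- phase_dnms(ev)
  expect_equal(got$parent_of_origin, "paternal")
  expect_equal(got$n_informative, 2)   # the G read is carried by both parents
})

test_that("reads on the non-mutant haplotype phase to the opposite parent", {
  # allele A private to the father seen only on reads without the mutation:
  # the mutation rode the maternal haplotype
  ev <- make_evidence("d1", c("A", "A"), c(FALSE, FALSE), "A/G", "G/G")
  expect_equal(phase_dnms(ev)$parent_of_origin, "maternal")
})

test_that("conflicting or uninformative evidence yields unphased", {
  conflict <- make_evidence("d1", c("A", "G"), c(TRUE, TRUE), "A/C", "G/C")
  got <- phase_dnms(conflict)
  expect_equal(got$parent_of_origin, "unphased")
  expect_true(got$conflicted)

  both <- make_evidence("d2", c("A", "A"), c(TRUE, TRUE), "A/G", "A/C")
  got2 <- phase_dnms(both)
  expect_equal(got2$parent_of_origin, "unphased")
  expect_equal(got2$n_informative, 0)
})

test_that("a phased call is never contradicted by any single observation", {
  set.seed(77)
  dnms <- tibble::tibble(
    dnm_id = paste0("d", 1:300), pos = seq_len(300) * 10L,
    parent_of_origin = sample(c("paternal", "maternal"), 300, TRUE),
    has_evidence = TRUE
  )
  ev <- simulate_phasing_evidence(dnms, conflict_prob = 0.15, seed = 8)
  got <- phase_dnms(ev)
  joined <- dplyr::inner_join(ev, got, by = "dnm_id")
  inf <- joined[joined$parent_of_origin != "unphased", ]
  # recompute each observation's vote and check none opposes the call
  vote <- ifelse(xor(inf$father_gt == "A/G", inf$dnm_allele_present),
                 "maternal", "paternal")
  informative <- inf$linked_allele == "A"
  expect_true(all(vote[informative] == inf$parent_of_origin[informative]))
})

test_that("alpha arithmetic, reciprocity and degenerate counts", {
  even <- alpha_from_counts(tibble::tibble(n_paternal = 30, n_maternal = 30))
  expect_equal(even$alpha, 1.0)
  expect_false(even$low_confidence)

  got <- alpha_from_counts(tibble::tibble(n_paternal = 70, n_maternal = 30))
  expect_equal(got$alpha, 2.333, tolerance = 1e-3)
  expect_true(got$ci_low <= got$alpha && got$alpha <= got$ci_high)

  # swapping counts inverts alpha and its interval
  swap <- alpha_from_counts(tibble::tibble(n_paternal = 30, n_maternal = 70))
  expect_equal(swap$alpha, 1 / got$alpha)
  expect_equal(swap$ci_low, 1 / got$ci_high, tolerance = 1e-10)
  expect_equal(swap$ci_high, 1 / got$ci_low, tolerance = 1e-10)

  none <- alpha_from_counts(tibble::tibble(n_paternal = 40, n_maternal = 0))
  expect_equal(none$alpha, Inf)
  expect_true(is.finite(none$ci_low))

  small <- alpha_from_counts(tibble::tibble(n_paternal = 5, n_maternal = 4))
  expect_true(small$low_confidence)
  expect_error(alpha_from_counts(tibble::tibble(n_paternal = 0,
                                                n_maternal = 0)),
               "at least one")
})

test_that("alpha interval covers the generating male bias", {
  set.seed(4242)
  p_true <- 0.70; alpha_true <- p_true / (1 - p_true)
  reps <- 200; n_phased <- 120
  covered <- 0
  for (r in seq_len(reps)) {
    n_pat <- rbinom(1, n_phased, p_true)
    est <- alpha_from_counts(tibble::tibble(n_paternal = n_pat,
                                            n_maternal = n_phased - n_pat))
    if (est$ci_low <= alpha_true && alpha_true <= est$ci_high) {
      covered <- covered + 1
    }
  }
  expect_gte(covered / reps, 0.90)
})

test_that("sibling sharing counts identical mutations within families", {
  dnms <- tibble::tibble(
    family_id = c("f1", "f1", "f1", "f1", "f2", "f2"),
    trio_id   = c("a",  "b",  "a",  "b",  "c",  "d"),
    chrom = "chr1",
    pos   = c(10L, 10L, 20L, 30L, 40L, 50L),
    alt   = c("T", "T", "C", "C", "G", "G")
  )
  got <- sibling_sharing(dnms)
  # pos 10 shared by a and b; pos 20/30 differ in position, 40/50 likewise
  expect_equal(got$n_instances, 6)
  expect_equal(got$n_shared, 2)
  expect_equal(got$shared_fraction, 1 / 3)
  expect_equal(got$se, sqrt((1 / 3) * (2 / 3) / 6))

  disjoint <- dnms[3:6, ]
  got0 <- sibling_sharing(disjoint)
  expect_equal(got0$shared_fraction, 0)

  solo <- tibble::tibble(family_id = "f", trio_id = "x", chrom = "chr1",
                         pos = 1L, alt = "A")
  expect_error(sibling_sharing(solo), "siblings")
})

test_that("binomial arithmetic of the shared fraction", {
  # 100 instances, 12 shared -> 12% with s.e. 3.25%
  f <- 12 / 100
  expect_equal(sqrt(f * (1 - f) / 100), 0.0325, tolerance = 1e-3)
})

test_that("sharing estimate tracks the generating duplication probability", {
  sp <- tiny_species(seed = 9, n_trios_total = 40)
  cfg <- sim_config(sibling_share_prob = 0.10, species_params = sp, seed = 9)
  co <- simulate_cohort(cfg)
  got <- sibling_sharing(co$dnms)
  # duplication with probability q makes ~2q/(2+q) of family instances shared
  expected <- 2 * 0.10 / (2 + 0.10)
  ci <- wilson_interval(got$n_shared, got$n_instances)
  expect_true(ci$low <= expected && expected <= ci$high)
})

test_that("phased fraction recovers the generating paternal fraction", {
  set.seed(55)
  covered <- 0; reps <- 60
  for (r in seq_len(reps)) {
    dnms <- tibble::tibble(
      dnm_id = paste0("d", 1:150), pos = seq_len(150) * 3L,
      parent_of_origin = c("maternal", "paternal")[1 + (runif(150) < 0.7)],
      has_evidence = TRUE
    )
    ev <- simulate_phasing_evidence(dnms, seed = 1000 + r)
    ph <- phase_dnms(ev)
    n_pat <- sum(ph$parent_of_origin == "paternal")
    n_tot <- sum(ph$parent_of_origin != "unphased")
    ci <- wilson_interval(n_pat, n_tot)
    if (ci$low <= 0.7 && 0.7 <= ci$high) covered <- covered + 1
  }
  expect_gte(covered / reps, 0.90)
})
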