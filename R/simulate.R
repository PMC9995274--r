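#' Configuration for the synthetic trio cohort generator
#'
#' Bundles every knob of the generator. Defaults describe a vertebrate
#' pedigree-sequencing cohort: 68 species (36 mammals, 18 birds, 8 fishes,
#' 6 reptiles) contributing 151 trios sequenced to a mean depth of 67x, a
#' per-generation mutation rate near 1.2e-8 with a paternal fraction of 0.7,
#' an age model with intercept 0.6e-8 mutations per site at birth and slope
#' 0.4e-9 per year of weighted parental age, 48% of mutations phaseable and
#' a 2% sibling-sharing probability. Site-level tables are generated at a
#' desk-scale number of sites (`n_sites`); the count-level cohort generator
#' instead uses the full callable genome size (`callable_genome`).
#'
#' @param n_sites number of genomic sites materialised per trio by
#'   [simulate_trio()].
#' @param mu_true per-site per-generation mutation rate used to plant de
#'   novo mutations.
#' @param paternal_fraction_true probability a planted mutation is paternal.
#' @param mean_depth expected sequencing depth per individual.
#' @param gq_mean,gq_sd parameters of the (truncated, rounded) normal
#'   genotype-quality distribution.
#' @param error_site_rate fraction of non-mutated sites given
#'   genotyping-error signatures (out-of-threshold annotations, skewed
#'   allele balance, depth or quality anomalies, or non-Mendelian
#'   genotypes).
#' @param het_site_rate fraction of sites with a transmitted heterozygote
#'   pattern (one parent HomRef, the other HomAlt, offspring Het); these
#'   drive the empirical allelic-balance component of the FNR.
#' @param sibling_share_prob probability a mutation is duplicated into a
#'   sibling of the same parent pair.
#' @param ab_noise standard deviation of the offspring allele-balance
#'   distribution around 0.5 (0 = pure binomial read sampling).
#' @param noise when `FALSE`, annotation, quality and depth values are
#'   clamped to mid-range so that no true mutation is lost to any filter
#'   (useful for recall tests); the default `TRUE` draws them from their
#'   null distributions, which induces a genuine false-negative rate.
#' @param phase_prob probability a mutation has phasing evidence.
#' @param a_true,b_true intercept (mutations per site at birth) and slope
#'   (per year of weighted age) of the generating age model.
#' @param species_effect_sd log-scale spread of multiplicative per-species
#'   rate deviations.
#' @param callable_genome callable sites per trio used by the count-level
#'   generator.
#' @param age_corr correlation between log paternal and log maternal age.
#' @param prob_age_missing fraction of trios whose parental ages are masked.
#' @param fnr_low,fnr_high range of the per-trio false-negative rates drawn
#'   in count mode.
#' @param spectrum_probs named probabilities of the six strand-collapsed
#'   mutation classes.
#' @param cpg_given_sw probability a C>T mutation sits in a CpG context.
#' @param seed integer random seed; a fixed seed makes every generator
#'   output reproducible.
#' @param species_params optional species table (see
#'   [default_species_params()]); built from the seed when `NULL`.
#' @param tree_params list with `crown_age` (Myr) for the random ultrametric
#'   tree.
#' @return A list of class `gmr_sim_config`.
#' @export
sim_config <- function(n_sites = 2e5,
                       mu_true = 1.2e-8,
                       paternal_fraction_true = 0.7,
                       mean_depth = 67,
                       gq_mean = 85, gq_sd = 10,
                       error_site_rate = 1e-4,
                       het_site_rate = 1e-3,
                       sibling_share_prob = 0.02,
                       ab_noise = 0.05,
                       noise = TRUE,
                       phase_prob = 0.48,
                       a_true = 0.6e-8,
                       b_true = 0.4e-9,
                       species_effect_sd = 0.15,
                       callable_genome = 2.4e9,
                       age_corr = 0.9,
                       prob_age_missing = 0.30,
                       fnr_low = 0.04, fnr_high = 0.07,
                       spectrum_probs = c("A>C" = 0.050, "A>G" = 0.215,
                                          "A>T" = 0.070, "C>A" = 0.080,
                                          "C>G" = 0.100, "C>T" = 0.485),
                       cpg_given_sw = 0.424,
                       seed = 1,
                       species_params = NULL,
                       tree_params = list(crown_age = 400)) {
  check_that(n_sites >= 1, "`n_sites` must be positive")
  check_that(mu_true >= 0 && mu_true < 1e-3,
             "`mu_true` must be a small non-negative per-site rate")
  check_that(paternal_fraction_true >= 0 && paternal_fraction_true <= 1,
             "`paternal_fraction_true` must lie in [0, 1]")
  check_that(mean_depth > 0, "`mean_depth` must be positive")
  check_that(error_site_rate >= 0 && error_site_rate < 1,
             "`error_site_rate` must lie in [0, 1)")
  check_that(sibling_share_prob >= 0 && sibling_share_prob <= 1,
             "`sibling_share_prob` must lie in [0, 1]")
  check_that(abs(sum(spectrum_probs) - 1) < 1e-8,
             "`spectrum_probs` must sum to 1")
  check_that(length(seed) == 1 && is.finite(seed),
             "`seed` must be a single integer")
  structure(
    list(n_sites = as.integer(n_sites), mu_true = mu_true,
         paternal_fraction_true = paternal_fraction_true,
         mean_depth = mean_depth, gq_mean = gq_mean, gq_sd = gq_sd,
         error_site_rate = error_site_rate, het_site_rate = het_site_rate,
         sibling_share_prob = sibling_share_prob, ab_noise = ab_noise,
         noise = noise, phase_prob = phase_prob,
         a_true = a_true, b_true = b_true,
         species_effect_sd = species_effect_sd,
         callable_genome = callable_genome, age_corr = age_corr,
         prob_age_missing = prob_age_missing,
         fnr_low = fnr_low, fnr_high = fnr_high,
         spectrum_probs = spectrum_probs, cpg_given_sw = cpg_given_sw,
         seed = as.integer(seed), species_params = species_params,
         tree_params = tree_params),
    class = "gmr_sim_config"
  )
}

# deterministic per-trio seed derived from the config seed and trio label
trio_seed <- function(seed, trio_id) {
  h <- sum(utf8ToInt(as.character(trio_id)) *
             seq_along(utf8ToInt(as.character(trio_id))))
  as.integer((as.numeric(seed) * 7919 + h) %% 2147483647L)
}

#' Simulate an all-sites genotype table for one trio
#'
#' Generates `n_sites` site records with the statistical structure the
#' calling and rate modules assume. De novo sites are drawn
#' `Binomial(2 n_sites, mu_true)` with parent of origin
#' `Bernoulli(paternal_fraction_true)`; depth is Poisson around
#' `mean_depth`; the offspring allele count at heterozygous sites is
#' binomial around an allele balance centred on 0.5 with spread `ab_noise`;
#' site annotations at well-behaved sites follow the null distributions the
#' FNR correction assumes (MQRankSum and ReadPosRankSum standard normal, FS
#' phred-scaled uniform, QD/MQ/SOR safely inside their thresholds); error
#' sites receive an out-of-threshold annotation, a skewed allele balance, a
#' depth or quality anomaly, or a non-Mendelian genotype. Output is
#' deterministic given the config seed and trio id.
#'
#' @param config a [sim_config()].
#' @param trio_id label for this trio.
#' @return A list with `sites` (tibble, one row per site; 0-based `pos`) and
#'   `truth` (tibble of planted de novo mutations with parent of origin,
#'   sibling-sharing flag and trinucleotide context).
#' @export
simulate_trio <- function(config = sim_config(), trio_id = "trio1") {
  check_that(inherits(config, "gmr_sim_config"), "`config` must be a sim_config()")
  n <- config$n_sites
  check_that(n >= 1, "cannot simulate a trio with zero sites")
  if (config$mu_true > 0 && config$mu_true * 2 * n < 1) {
    warn(sprintf("expected planted mutation count %.3g < 1; most trios will carry none",
                 config$mu_true * 2 * n))
  }
  set.seed(trio_seed(config$seed, trio_id))

  n_dnm <- rbinom(1, 2L * n, config$mu_true)
  n_err <- rbinom(1, n, config$error_site_rate)
  n_het <- rbinom(1, n, config$het_site_rate)
  n_special <- n_dnm + n_err + n_het
  check_that(n_special <= n, "n_sites too small for the requested rates")
  special <- sample.int(n, n_special)
  idx_dnm <- special[seq_len(n_dnm)]
  idx_err <- special[seq_len(n_err) + n_dnm]
  idx_het <- special[seq_len(n_het) + n_dnm + n_err]

  rint <- function(m, sdev) pmax(0L, pmin(99L, as.integer(round(rnorm(n, m, sdev)))))
  if (config$noise) {
    dp_f <- rpois(n, config$mean_depth); dp_m <- rpois(n, config$mean_depth)
    dp_o <- rpois(n, config$mean_depth)
    gq_f <- rint(config$gq_mean, config$gq_sd)
    gq_m <- rint(config$gq_mean, config$gq_sd)
    gq_o <- rint(config$gq_mean, config$gq_sd)
    qd <- runif(n, 15, 30)
    fs <- -10 * log10(runif(n))
    mq <- runif(n, 50, 60)
    mqrs <- rnorm(n)
    rprs <- rnorm(n)
    sor <- runif(n, 0.5, 2.5)
  } else {
    dpc <- as.integer(round(config$mean_depth))
    dp_f <- dp_m <- dp_o <- rep(dpc, n)
    gq_f <- gq_m <- gq_o <- rep(80L, n)
    qd <- rep(20, n); fs <- rep(1, n); mq <- rep(55, n)
    mqrs <- rep(0, n); rprs <- rep(0, n); sor <- rep(1, n)
  }

  ref <- sample(BASES, n, replace = TRUE)
  alt <- rep(NA_character_, n)
  gt_f <- gt_m <- gt_o <- rep("HomRef", n)
  ad_ref_f <- dp_f; ad_alt_f <- integer(n)
  ad_ref_m <- dp_m; ad_alt_m <- integer(n)
  ad_ref_o <- dp_o; ad_alt_o <- integer(n)

  draw_ab <- function(k) {
    if (config$ab_noise <= 0) return(rep(0.5, k))
    v <- config$ab_noise^2
    shape <- max((1 / (4 * v) - 1) / 2, 0.5)
    rbeta(k, shape, shape)
  }
  other_base <- function(r) {
    vapply(r, function(b) sample(setdiff(BASES, b), 1), character(1))
  }
  plant_het_offspring <- function(idx) {
    k <- length(idx)
    ab <- if (config$noise) draw_ab(k) else rep(0.5, k)
    alt_reads <- rbinom(k, dp_o[idx], ab)
    ad_alt_o[idx] <<- alt_reads
    ad_ref_o[idx] <<- dp_o[idx] - alt_reads
    gt_o[idx] <<- "Het"
  }

  context <- character(0)
  if (n_dnm > 0) {
    alt[idx_dnm] <- other_base(ref[idx_dnm])
    plant_het_offspring(idx_dnm)
    context <- paste0(sample(BASES, n_dnm, TRUE), ref[idx_dnm],
                      sample(BASES, n_dnm, TRUE))
  }
  if (n_het > 0) {
    alt[idx_het] <- other_base(ref[idx_het])
    father_is_alt <- runif(n_het) < 0.5
    gt_f[idx_het][father_is_alt] <- "HomAlt"
    gt_m[idx_het][!father_is_alt] <- "HomAlt"
    fa <- idx_het[father_is_alt]; mo <- idx_het[!father_is_alt]
    ad_alt_f[fa] <- dp_f[fa]; ad_ref_f[fa] <- 0L
    ad_alt_m[mo] <- dp_m[mo]; ad_ref_m[mo] <- 0L
    plant_het_offspring(idx_het)
  }
  if (n_err > 0) {
    alt[idx_err] <- other_base(ref[idx_err])
    plant_het_offspring(idx_err)
    modes <- sample(c("qd", "fs", "mq", "mqrs", "rprs", "sor",
                      "ab", "gq", "dp", "mendelian"), n_err, replace = TRUE)
    for (j in seq_len(n_err)) {
      i <- idx_err[j]
      switch(modes[j],
        qd = { qd[i] <- runif(1, 0, 1.9) },
        fs = { fs[i] <- runif(1, 21, 60) },
        mq = { mq[i] <- runif(1, 20, 39) },
        mqrs = { mqrs[i] <- sample(c(-1, 1), 1) *
                   runif(1, 4.5, 8) },
        rprs = { rprs[i] <- sample(c(-1, 1), 1) * runif(1, 3.5, 6) },
        sor = { sor[i] <- runif(1, 3.2, 6) },
        ab = { k <- rbinom(1, dp_o[i], 0.1)
               ad_alt_o[i] <- k; ad_ref_o[i] <- dp_o[i] - k },
        gq = { gq_o[i] <- as.integer(runif(1, 0, 59)) },
        dp = { dp_o[i] <- as.integer(round(3 * config$mean_depth))
               ad_ref_o[i] <- dp_o[i] - ad_alt_o[i] },
        mendelian = { gt_f[i] <- "Het"
                      ad_alt_f[i] <- as.integer(round(dp_f[i] / 2))
                      ad_ref_f[i] <- dp_f[i] - ad_alt_f[i] }
      )
    }
  }

  sites <- tibble(
    trio_id = trio_id,
    chrom = "chr1",
    pos = 0:(n - 1L),
    ref = ref, alt = alt,
    gt_father = gt_f, gt_mother = gt_m, gt_offspring = gt_o,
    ad_ref_father = as.integer(ad_ref_f), ad_alt_father = as.integer(ad_alt_f),
    ad_ref_mother = as.integer(ad_ref_m), ad_alt_mother = as.integer(ad_alt_m),
    ad_ref_offspring = as.integer(ad_ref_o),
    ad_alt_offspring = as.integer(ad_alt_o),
    dp_father = as.integer(dp_f), dp_mother = as.integer(dp_m),
    dp_offspring = as.integer(dp_o),
    gq_father = as.integer(gq_f), gq_mother = as.integer(gq_m),
    gq_offspring = as.integer(gq_o),
    qd = qd, fs = fs, mq = mq,
    mq_rank_sum = mqrs, read_pos_rank_sum = rprs, sor = sor
  )
  truth <- tibble(
    trio_id = trio_id,
    chrom = "chr1",
    pos = sort(idx_dnm) - 1L,
    ref = ref[sort(idx_dnm)],
    alt = alt[sort(idx_dnm)],
    parent_of_origin = c("maternal", "paternal")[
      1L + (runif(n_dnm) < config$paternal_fraction_true)],
    shared_with_sibling = runif(n_dnm) < config$sibling_share_prob,
    context = context[order(idx_dnm)]
  )
  list(sites = sites, truth = truth)
}

#' Default species table for the cohort generator
#'
#' Builds a species table mirroring a broad vertebrate pedigree cohort: 68
#' species split 36/18/8/6 across mammals, birds, fishes and reptiles, 151
#' trios in total, class-level paternal fractions implying male biases near
#' 2.3 (mammals), 3.2 (birds), 1.5 (reptiles) and 0.8 (fishes), log-normal
#' generation times, 22 domesticated species, and life-history traits
#' (maturation time, longevity, offspring per generation, body mass)
#' correlated with generation time.
#'
#' @param n_mammals,n_birds,n_fishes,n_reptiles species counts per class.
#' @param n_trios_total total trios distributed over species (each species
#'   gets at least one).
#' @param n_domesticated number of species flagged domesticated.
#' @param seed integer seed.
#' @return A tibble with one row per species.
#' @export
default_species_params <- function(n_mammals = 36, n_birds = 18,
                                   n_fishes = 8, n_reptiles = 6,
                                   n_trios_total = 151,
                                   n_domesticated = 22, seed = 1) {
  set.seed(trio_seed(seed, "species-params"))
  classes <- rep(c("mammals", "birds", "fishes", "reptiles"),
                 c(n_mammals, n_birds, n_fishes, n_reptiles))
  n_sp <- length(classes)
  check_that(n_trios_total >= n_sp, "need at least one trio per species")
  gen_pars <- list(
    mammals = c(log(6), 0.9), birds = c(log(6), 0.7),
    fishes = c(log(3), 0.6), reptiles = c(log(4), 0.9)
  )
  g <- vapply(classes, function(cl) {
    p <- gen_pars[[cl]]
    min(max(exp(rnorm(1, p[1], p[2])), 0.3), 30)
  }, numeric(1))
  p_class <- c(mammals = 2.3, birds = 3.2, fishes = 0.8, reptiles = 1.5)
  p_class <- p_class / (1 + p_class)
  extra <- table(factor(sample(n_sp, n_trios_total - n_sp, replace = TRUE),
                        levels = seq_len(n_sp)))
  dom_pool <- which(classes %in% c("mammals", "birds"))
  dom <- rep(FALSE, n_sp)
  dom[sample(dom_pool, min(n_domesticated, length(dom_pool)))] <- TRUE
  tibble(
    species = sprintf("sp%02d", seq_len(n_sp)),
    class = classes,
    generation_time = unname(g),
    paternal_fraction = unname(p_class[classes]),
    n_trios = as.integer(1 + extra),
    domesticated = dom,
    maturation_time = unname(g) * exp(rnorm(n_sp, log(0.5), 0.3)),
    longevity = unname(g) * exp(rnorm(n_sp, log(3), 0.4)),
    fecundity = exp(rnorm(n_sp, log(5) - 0.5 * log(unname(g)), 0.6)),
    body_mass = exp(rnorm(n_sp, 2 + 1.5 * log(unname(g)), 1.5))
  )
}

#' Simulate a multi-species trio cohort
#'
#' Generates a full cohort: per-trio metadata with correlated parental ages,
#' de novo counts (count mode) or all-sites tables (site mode), a mutation
#' table with classes, contexts, parental origins and sibling duplicates, a
#' random ultrametric species tree, and piecewise-constant Ne trajectories.
#'
#' In count mode, the trio's mutation count is drawn Poisson with mean
#' `(1 - FNR) * 2 * C * d_s * (a_true + b_true * tau)`, where `tau` is the
#' weighted parental age and `d_s` a log-normal species deviation — the same
#' generative model the age-model module fits. In site mode each trio gets a
#' materialised site table from [simulate_trio()] and the mutation count is
#' whatever was planted.
#'
#' Sibling sharing: species with two or more trios are treated as families
#' of full siblings with probability one half; within a family, each
#' mutation is duplicated into one random sibling with probability
#' `sibling_share_prob`.
#'
#' @param config a [sim_config()].
#' @param mode `"counts"` (study-scale counts, no site tables) or `"sites"`
#'   (desk-scale site tables per trio).
#' @return An object of class `gmr_cohort`: list with `trios`, `species`,
#'   `dnms`, `tree` (`phylo`), `ne`, `truth`, `sites` (named list of site
#'   tables in site mode), `config`.
#' @export
simulate_cohort <- function(config = sim_config(),
                            mode = c("counts", "sites")) {
  mode <- match.arg(mode)
  check_that(inherits(config, "gmr_sim_config"), "`config` must be a sim_config()")
  sp <- config$species_params
  if (is.null(sp)) sp <- default_species_params(seed = config$seed)
  check_that(nrow(sp) >= 2,
             "at least two species are required (the cohort carries a tree)")
  check_that(all(!is.na(sp$generation_time) & sp$generation_time > 0),
             "every species needs a positive generation time")
  if (!"n_trios" %in% names(sp)) sp$n_trios <- 1L
  if (!"paternal_fraction" %in% names(sp)) {
    sp$paternal_fraction <- config$paternal_fraction_true
  }
  set.seed(trio_seed(config$seed, "cohort"))

  # trio metadata with correlated log-normal parental ages
  trios <- sp |>
    select("species", "class", "generation_time", "paternal_fraction",
           "n_trios", dplyr::any_of("domesticated")) |>
    tidyr::uncount(.data$n_trios) |>
    mutate(trio_id = sprintf("%s_t%d", .data$species,
                             sequence(rle(.data$species)$lengths)))
  n_t <- nrow(trios)
  z_m <- rnorm(n_t, 0, 0.35)
  z_f <- config$age_corr * z_m +
    sqrt(1 - config$age_corr^2) * rnorm(n_t, 0, 0.35)
  trios$mother_age <- trios$generation_time * exp(z_m)
  trios$father_age <- trios$generation_time * exp(z_f)
  ages_known <- runif(n_t) >= config$prob_age_missing
  trios$ages_known <- ages_known

  # family structure for sibling sharing
  trios <- trios |>
    group_by(.data$species) |>
    mutate(family_id = if (n() >= 2 && runif(1) < 0.5)
      paste0(.data$species[1], "_fam") else paste0(.data$trio_id, "_fam")) |>
    ungroup()

  # species deviations of the generating model
  sp$d_s <- exp(rnorm(nrow(sp), 0, config$species_effect_sd))
  trios$d_s <- sp$d_s[match(trios$species, sp$species)]

  tau <- trios$paternal_fraction * trios$father_age +
    (1 - trios$paternal_fraction) * trios$mother_age

  sites_list <- NULL
  truth_sites <- NULL
  if (mode == "counts") {
    trios$n_callable <- round(config$callable_genome *
                                exp(rnorm(n_t, 0, 0.05)))
    trios$fnr <- runif(n_t, config$fnr_low, config$fnr_high)
    lambda <- (1 - trios$fnr) * 2 * trios$n_callable * trios$d_s *
      (config$a_true + config$b_true * tau)
    trios$m <- rpois(n_t, lambda)
  } else {
    sims <- lapply(trios$trio_id, function(id) simulate_trio(config, id))
    names(sims) <- trios$trio_id
    sites_list <- lapply(sims, `[[`, "sites")
    truth_sites <- bind_rows(lapply(sims, `[[`, "truth"))
    sites_list <- share_planted_dnms(sites_list, truth_sites, trios)
    trios$m <- vapply(trios$trio_id, function(id)
      sum(truth_sites$trio_id == id), integer(1))
    trios$n_callable <- NA_real_
    trios$fnr <- NA_real_
  }

  # mutation table (classes, contexts, origins, sibling duplicates)
  set.seed(trio_seed(config$seed, "cohort-dnms"))
  dnms <- cohort_dnm_table(trios, config)

  # phased counts per trio from the mutation table
  phased <- dnms |>
    group_by(.data$trio_id) |>
    summarise(
      n_paternal = sum(.data$parent_of_origin == "paternal" & .data$has_evidence),
      n_maternal = sum(.data$parent_of_origin == "maternal" & .data$has_evidence),
      .groups = "drop"
    )
  trios <- trios |>
    left_join(phased, by = "trio_id") |>
    mutate(n_paternal = tidyr::replace_na(.data$n_paternal, 0L),
           n_maternal = tidyr::replace_na(.data$n_maternal, 0L))

  # ultrametric random tree scaled to the crown age
  set.seed(trio_seed(config$seed, "cohort-tree"))
  tree <- ape::rcoal(nrow(sp), tip.label = sp$species)
  depth <- max(ape::node.depth.edgelength(tree))
  tree$edge.length <- tree$edge.length / depth * config$tree_params$crown_age

  # piecewise-constant Ne histories
  ne <- purrr::map_dfr(sp$species, function(s) {
    breaks <- exp(seq(log(1e4), log(2e6), length.out = 9))
    base <- exp(rnorm(1, log(2e4), 0.5))
    tibble(species = s,
           t_start = c(0, breaks[-9]),
           t_end = breaks,
           ne = base * exp(rnorm(9, 0, 0.4)))
  })

  out_trios <- trios |>
    mutate(father_age = ifelse(.data$ages_known, .data$father_age, NA_real_),
           mother_age = ifelse(.data$ages_known, .data$mother_age, NA_real_)) |>
    select("trio_id", "species", "class", "family_id", "generation_time",
           "father_age", "mother_age", "ages_known",
           dplyr::any_of(c("domesticated")), "paternal_fraction",
           "n_callable", "fnr", "m", "n_paternal", "n_maternal")

  structure(
    list(
      trios = out_trios,
      species = sp,
      dnms = dnms,
      tree = tree,
      ne = ne,
      truth = list(
        a_true = config$a_true, b_true = config$b_true,
        mu_true = config$mu_true,
        paternal_fraction_true = config$paternal_fraction_true,
        species_deviation = sp |> select("species", "d_s"),
        latent_ages = trios |> select("trio_id", "father_age", "mother_age"),
        planted = truth_sites
      ),
      sites = sites_list,
      config = config
    ),
    class = "gmr_cohort"
  )
}

# duplicate shared planted mutations into one sibling's site table
share_planted_dnms <- function(sites_list, truth_sites, trios) {
  shared <- truth_sites[truth_sites$shared_with_sibling, , drop = FALSE]
  if (nrow(shared) == 0) return(sites_list)
  fam <- split(trios$trio_id, trios$family_id)
  fam <- fam[vapply(fam, length, integer(1)) >= 2]
  sib_of <- function(id) {
    f <- fam[[trios$family_id[match(id, trios$trio_id)]]]
    if (is.null(f) || length(f) < 2) return(NA_character_)
    sample(setdiff(f, id), 1)
  }
  for (r in seq_len(nrow(shared))) {
    sib <- sib_of(shared$trio_id[r])
    if (is.na(sib)) next
    tbl <- sites_list[[sib]]
    i <- match(shared$pos[r], tbl$pos)
    donor <- sites_list[[shared$trio_id[r]]]
    j <- match(shared$pos[r], donor$pos)
    cols <- setdiff(names(tbl), c("trio_id"))
    tbl[i, cols] <- donor[j, cols]
    sites_list[[sib]] <- tbl
  }
  sites_list
}

# per-mutation table for a cohort: classes, contexts, origins, sibling copies
cohort_dnm_table <- function(trios, config) {
  probs <- config$spectrum_probs
  make_one <- function(trio) {
    m <- trio$m
    if (m == 0) return(NULL)
    cls <- sample(names(probs), m, replace = TRUE, prob = probs)
    ref0 <- substr(cls, 1, 1)
    alt0 <- substr(cls, 3, 3)
    nxt <- ifelse(ref0 == "C" & alt0 == "T",
                  ifelse(runif(m) < config$cpg_given_sw, "G",
                         sample(c("A", "C", "T"), m, replace = TRUE)),
                  sample(BASES, m, replace = TRUE))
    prev <- sample(BASES, m, replace = TRUE)
    ctx <- paste0(prev, ref0, nxt)
    # random strand presentation
    flip <- runif(m) < 0.5
    ref <- ifelse(flip, complement_base(ref0), ref0)
    alt <- ifelse(flip, complement_base(alt0), alt0)
    ctx[flip] <- reverse_complement(ctx[flip])
    tibble(
      trio_id = trio$trio_id, species = trio$species, group = trio$class,
      family_id = trio$family_id,
      chrom = "chr1",
      pos = sample.int(2^30, m),
      ref = ref, alt = alt, context = ctx,
      parent_of_origin = ifelse(
        runif(m) < trio$paternal_fraction, "paternal", "maternal"),
      has_evidence = runif(m) < config$phase_prob,
      shared_copy = FALSE
    )
  }
  d <- purrr::map_dfr(seq_len(nrow(trios)), function(i) make_one(trios[i, ]))
  if (nrow(d) == 0) return(d)
  # sibling duplicates within multi-trio families
  fams <- split(trios$trio_id, trios$family_id)
  fams <- fams[vapply(fams, length, integer(1)) >= 2]
  if (length(fams) > 0 && config$sibling_share_prob > 0) {
    in_fam <- d$family_id %in% names(fams)
    dup <- in_fam & runif(nrow(d)) < config$sibling_share_prob
    if (any(dup)) {
      copies <- d[dup, , drop = FALSE]
      copies$trio_id <- vapply(seq_len(nrow(copies)), function(r) {
        sibs <- setdiff(fams[[copies$family_id[r]]], copies$trio_id[r])
        sample(sibs, 1)
      }, character(1))
      copies$shared_copy <- TRUE
      d <- bind_rows(d, copies)
    }
  }
  d$dnm_id <- sprintf("%s:%s:%d", d$trio_id, d$chrom, d$pos)
  d
}

#' Simulate read-backed phasing evidence for a mutation table
#'
#' For each mutation flagged `has_evidence`, emits one or more linkage
#' observations consistent with its true parent of origin: reads carrying
#' the de novo allele also carry a heterozygous-site allele private to that
#' parent, and reads carrying the other offspring haplotype carry the allele
#' shared with the other parent. A conflict probability can corrupt single
#' observations to exercise the strict conflict rule.
#'
#' @param dnms a mutation table from [simulate_cohort()] (needs `dnm_id`,
#'   `parent_of_origin`, `has_evidence`).
#' @param conflict_prob probability an observation's linked allele is
#'   flipped.
#' @param mean_obs mean number of extra observations per mutation beyond the
#'   first.
#' @param seed integer seed.
#' @return An evidence tibble for [phase_dnms()].
#' @export
simulate_phasing_evidence <- function(dnms, conflict_prob = 0,
                                      mean_obs = 2, seed = 1) {
  check_that(all(c("dnm_id", "parent_of_origin", "has_evidence") %in%
                   names(dnms)),
             "`dnms` needs dnm_id, parent_of_origin, has_evidence columns")
  set.seed(trio_seed(seed, "phasing-evidence"))
  d <- dnms[dnms$has_evidence, , drop = FALSE]
  if (nrow(d) == 0) {
    return(tibble(dnm_id = character(0), read_id = character(0),
                  linked_pos = integer(0), linked_allele = character(0),
                  dnm_allele_present = logical(0), father_gt = character(0),
                  mother_gt = character(0), offspring_gt = character(0)))
  }
  purrr::map_dfr(seq_len(nrow(d)), function(i) {
    k <- 1 + rpois(1, mean_obs)
    pat <- d$parent_of_origin[i] == "paternal"
    # linked het site: allele "A" private to the mutation's parent of origin
    father_gt <- if (pat) "A/G" else "G/G"
    mother_gt <- if (pat) "G/G" else "A/G"
    on_dnm_hap <- runif(k) < 0.5
    allele <- ifelse(on_dnm_hap, "A", "G")
    flip <- runif(k) < conflict_prob
    allele[flip] <- ifelse(allele[flip] == "A", "G", "A")
    tibble(
      dnm_id = d$dnm_id[i],
      read_id = sprintf("%s_r%d", d$dnm_id[i], seq_len(k)),
      linked_pos = d$pos[i] + 50L,
      linked_allele = allele,
      dnm_allele_present = on_dnm_hap,
      father_gt = father_gt,
      mother_gt = mother_gt,
      offspring_gt = "A/G"
    )
  })
}

#' @export
print.gmr_cohort <- function(x, ...) {
  cat("Synthetic trio cohort:", nrow(x$trios), "trios,",
      nrow(x$species), "species\n")
  cat("  classes:", paste(sprintf("%s (%d)", names(table(x$species$class)),
                                  table(x$species$class)), collapse = ", "), "\n")
  cat("  mutations:", nrow(x$dnms),
      if (is.null(x$sites)) "(count mode)" else "(site mode)", "\n")
  invisible(x)
}
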