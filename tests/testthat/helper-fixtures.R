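# builders and independent oracles shared across test files

# one site row with every schema column; defaults are a clean nominal
# candidate de novo site (parents HomRef, offspring balanced Het)
make_site <- function(gt_father = "HomRef", gt_mother = "HomRef",
                      gt_offspring = "Het",
                      ad_offspring = c(30, 30), dp = c(60, 60, 60),
                      gq = c(70, 70, 70),
                      qd = 10, fs = 3, mq = 60, mq_rank_sum = 0,
                      read_pos_rank_sum = 0, sor = 1,
                      pos = 0, ref = "A", alt = "G") {
  tibble::tibble(
    trio_id = "t1", chrom = "chr1", pos = pos, ref = ref, alt = alt,
    gt_father = gt_father, gt_mother = gt_mother, gt_offspring = gt_offspring,
    ad_ref_father = dp[1], ad_alt_father = 0L,
    ad_ref_mother = dp[2], ad_alt_mother = 0L,
    ad_ref_offspring = ad_offspring[1], ad_alt_offspring = ad_offspring[2],
    dp_father = dp[1], dp_mother = dp[2], dp_offspring = dp[3],
    gq_father = gq[1], gq_mother = gq[2], gq_offspring = gq[3],
    qd = qd, fs = fs, mq = mq, mq_rank_sum = mq_rank_sum,
    read_pos_rank_sum = read_pos_rank_sum, sor = sor
  )
}

# a random site table exercising every filter axis, for oracle-equivalence
# property tests
random_site_table <- function(n, seed) {
  set.seed(seed)
  gts <- c("HomRef", "Het", "HomAlt", "Missing")
  dp <- function() sample(10:150, n, replace = TRUE)
  dpf <- dp(); dpm <- dp(); dpo <- dp()
  alt_reads <- rbinom(n, dpo, runif(n, 0.05, 0.95))
  tbl <- tibble::tibble(
    trio_id = "t1", chrom = "chr1", pos = seq_len(n) - 1L,
    ref = sample(c("A", "C", "G", "T"), n, TRUE),
    alt = sample(c("A", "C", "G", "T"), n, TRUE),
    gt_father = sample(gts, n, TRUE, prob = c(0.7, 0.1, 0.1, 0.1)),
    gt_mother = sample(gts, n, TRUE, prob = c(0.7, 0.1, 0.1, 0.1)),
    gt_offspring = sample(gts, n, TRUE, prob = c(0.4, 0.4, 0.1, 0.1)),
    ad_ref_father = dpf, ad_alt_father = 0L,
    ad_ref_mother = dpm, ad_alt_mother = 0L,
    ad_ref_offspring = dpo - alt_reads, ad_alt_offspring = alt_reads,
    dp_father = dpf, dp_mother = dpm, dp_offspring = dpo,
    gq_father = sample(0:99, n, TRUE), gq_mother = sample(0:99, n, TRUE),
    gq_offspring = sample(0:99, n, TRUE),
    qd = runif(n, 0, 40),
    fs = runif(n, 0, 40),
    mq = runif(n, 20, 70),
    mq_rank_sum = rnorm(n, 0, 3),
    read_pos_rank_sum = rnorm(n, 0, 2),
    sor = runif(n, 0, 6)
  )
  tbl[tbl$ref != tbl$alt, , drop = FALSE]
}

# independent scalar re-evaluation of the whole filter cascade, written as
# one literal predicate per filter (the brute-force oracle)
oracle_pass_one <- function(row, cfg, m_depth) {
  pass_ann <- TRUE
  if (!is.na(row$qd) && row$qd < cfg$qd_min) pass_ann <- FALSE
  if (!is.na(row$fs) && row$fs > cfg$fs_max) pass_ann <- FALSE
  if (!is.na(row$mq) && row$mq < cfg$mq_min) pass_ann <- FALSE
  if (!is.na(row$mq_rank_sum) &&
      (row$mq_rank_sum < cfg$mqrs_min || row$mq_rank_sum > cfg$mqrs_max))
    pass_ann <- FALSE
  if (!is.na(row$read_pos_rank_sum) &&
      (row$read_pos_rank_sum < cfg$rprs_min ||
       row$read_pos_rank_sum > cfg$rprs_max)) pass_ann <- FALSE
  if (!is.na(row$sor) && row$sor > cfg$sor_max) pass_ann <- FALSE

  mend <- row$gt_father == "HomRef" && row$gt_mother == "HomRef" &&
    row$gt_offspring == "Het"
  tot <- row$ad_ref_offspring + row$ad_alt_offspring
  ab_ok <- tot > 0 && {
    ab <- row$ad_alt_offspring / tot
    ab >= cfg$ab_min && ab <= cfg$ab_max
  }
  dp_ok <- all(c(row$dp_father, row$dp_mother, row$dp_offspring) >
                 cfg$dp_low_factor * m_depth &
               c(row$dp_father, row$dp_mother, row$dp_offspring) <
                 cfg$dp_high_factor * m_depth)
  gq_ok <- all(c(row$gq_father, row$gq_mother, row$gq_offspring) >=
                 cfg$gq_min)
  pass_ann && mend && ab_ok && dp_ok && gq_ok && !is.na(row$alt)
}

oracle_call <- function(sites, cfg) {
  m_depth <- mean(c(mean(sites$dp_father), mean(sites$dp_mother),
                    mean(sites$dp_offspring)))
  keep <- vapply(seq_len(nrow(sites)),
                 function(i) oracle_pass_one(sites[i, ], cfg, m_depth),
                 logical(1))
  sites[keep, , drop = FALSE]
}

# small species table for fast cohorts
tiny_species <- function(seed = 1, n_trios_total = 12) {
  default_species_params(n_mammals = 3, n_birds = 2, n_fishes = 1,
                         n_reptiles = 1, n_trios_total = n_trios_total,
                         n_domesticated = 2, seed = seed)
}
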