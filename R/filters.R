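#' Filter thresholds for trio de novo mutation calling
#'
#' Builds the configuration object holding every threshold of the five-filter
#' cascade: hard site-annotation cut-offs (filter 1), the Mendelian pattern
#' (filter 2, fixed: parents HomRef, offspring Het), the offspring allelic
#' balance window (filter 3), the per-individual depth window relative to the
#' mean trio depth (filter 4) and the genotype-quality floor (filter 5).
#'
#' Defaults follow common GATK hard-filtering practice for pedigree studies:
#' candidate sites are dropped when QD < 2, FS > 20, MQ < 40, MQRankSum
#' outside (-2, 4), ReadPosRankSum outside (-3, 3) or SOR > 3; the offspring
#' must carry the alternative allele on 30-70% of its reads (closed interval);
#' every individual must have `0.5 * m_depth < DP < 2 * m_depth` (strict) and
#' GQ >= 60.
#'
#' @param qd_min,fs_max,mq_min,mqrs_min,mqrs_max,rprs_min,rprs_max,sor_max
#'   site-annotation cut-offs (filter 1).
#' @param ab_min,ab_max closed allelic-balance window for the offspring
#'   alternative-allele read fraction (filter 3).
#' @param dp_low_factor,dp_high_factor multiples of the mean trio depth
#'   bounding each individual's DP, exclusive on both sides (filter 4).
#' @param gq_min minimum genotype quality for all three individuals
#'   (filter 5).
#' @return A list of class `gmr_filter_config`.
#' @examples
#' cfg <- filter_config()
#' cfg$gq_min
#' @export
filter_config <- function(qd_min = 2.0, fs_max = 20.0, mq_min = 40.0,
                          mqrs_min = -2.0, mqrs_max = 4.0,
                          rprs_min = -3.0, rprs_max = 3.0, sor_max = 3.0,
                          ab_min = 0.30, ab_max = 0.70,
                          dp_low_factor = 0.5, dp_high_factor = 2.0,
                          gq_min = 60) {
  cfg <- list(
    qd_min = qd_min, fs_max = fs_max, mq_min = mq_min,
    mqrs_min = mqrs_min, mqrs_max = mqrs_max,
    rprs_min = rprs_min, rprs_max = rprs_max, sor_max = sor_max,
    ab_min = ab_min, ab_max = ab_max,
    dp_low_factor = dp_low_factor, dp_high_factor = dp_high_factor,
    gq_min = gq_min
  )
  check_that(all(vapply(cfg, is.numeric, logical(1))) &&
               all(is.finite(unlist(cfg))),
             "all filter thresholds must be finite numbers")
  check_that(ab_min < ab_max, "`ab_min` must be smaller than `ab_max`")
  check_that(dp_low_factor < dp_high_factor,
             "`dp_low_factor` must be smaller than `dp_high_factor`")
  structure(cfg, class = "gmr_filter_config")
}

# required columns of a trio site table
site_table_columns <- function() {
  c("chrom", "pos", "ref", "alt",
    "gt_father", "gt_mother", "gt_offspring",
    "ad_ref_father", "ad_alt_father", "ad_ref_mother", "ad_alt_mother",
    "ad_ref_offspring", "ad_alt_offspring",
    "dp_father", "dp_mother", "dp_offspring",
    "gq_father", "gq_mother", "gq_offspring",
    "qd", "fs", "mq", "mq_rank_sum", "read_pos_rank_sum", "sor")
}

check_site_table <- function(sites) {
  missing <- setdiff(site_table_columns(), names(sites))
  check_that(length(missing) == 0,
             paste0("site table is missing columns: ",
                    paste(missing, collapse = ", ")))
  invisible(sites)
}

# Logical failure matrix for the site-annotation filters. A missing (NA)
# annotation never fails its own sub-filter: GATK omits the RankSum
# annotations at some sites and discarding those silently would deflate the
# callable genome.
site_failure_matrix <- function(sites, cfg) {
  fails_low  <- function(x, thr) !is.na(x) & x < thr
  fails_high <- function(x, thr) !is.na(x) & x > thr
  cbind(
    QD  = fails_low(sites$qd, cfg$qd_min),
    FS  = fails_high(sites$fs, cfg$fs_max),
    MQ  = fails_low(sites$mq, cfg$mq_min),
    MQRankSum = fails_low(sites$mq_rank_sum, cfg$mqrs_min) |
      fails_high(sites$mq_rank_sum, cfg$mqrs_max),
    ReadPosRankSum = fails_low(sites$read_pos_rank_sum, cfg$rprs_min) |
      fails_high(sites$read_pos_rank_sum, cfg$rprs_max),
    SOR = fails_high(sites$sor, cfg$sor_max)
  )
}

# Logical failure matrix for the trio-level filters (Mendelian pattern,
# allelic balance, depth window, genotype quality).
trio_failure_matrix <- function(sites, cfg, m_depth) {
  dnm_pattern <- sites$gt_father == "HomRef" & sites$gt_mother == "HomRef" &
    sites$gt_offspring == "Het"
  n_inf <- sites$ad_ref_offspring + sites$ad_alt_offspring
  ab <- ifelse(n_inf > 0, sites$ad_alt_offspring / n_inf, NA_real_)
  dp_ok <- function(dp) {
    !is.na(dp) & dp > cfg$dp_low_factor * m_depth &
      dp < cfg$dp_high_factor * m_depth
  }
  gq_ok <- function(gq) !is.na(gq) & gq >= cfg$gq_min
  cbind(
    mendelian = !dnm_pattern,
    AB = is.na(ab) | ab < cfg$ab_min | ab > cfg$ab_max,
    DP = !(dp_ok(sites$dp_father) & dp_ok(sites$dp_mother) &
             dp_ok(sites$dp_offspring)),
    GQ = !(gq_ok(sites$gq_father) & gq_ok(sites$gq_mother) &
             gq_ok(sites$gq_offspring))
  )
}

failure_matrix_to_verdicts <- function(fm) {
  failed <- apply(fm, 1, function(r) colnames(fm)[r], simplify = FALSE)
  tibble(passed = rowSums(fm) == 0, failed_filters = failed)
}

#' Apply the site-annotation filters to trio sites
#'
#' Evaluates filter 1 of the cascade: a site fails when any of QD, FS, MQ,
#' MQRankSum, ReadPosRankSum or SOR lies outside its configured bound.
#' A missing annotation does not fail the corresponding sub-filter.
#'
#' @param sites a trio site table (see [simulate_trio()] for the schema).
#' @param cfg a [filter_config()].
#' @return A tibble with one row per site: `passed` (logical) and
#'   `failed_filters` (list of character, the names of violated sub-filters).
#' @examples
#' s <- tibble::tibble(qd = c(1.5, 10), fs = 3, mq = 60, mq_rank_sum = 0,
#'                     read_pos_rank_sum = 0, sor = 1)
#' apply_site_filters(s, filter_config())
#' @export
apply_site_filters <- function(sites, cfg = filter_config()) {
  needed <- c("qd", "fs", "mq", "mq_rank_sum", "read_pos_rank_sum", "sor")
  missing <- setdiff(needed, names(sites))
  check_that(length(missing) == 0,
             paste0("site table is missing annotation columns: ",
                    paste(missing, collapse = ", ")))
  failure_matrix_to_verdicts(site_failure_matrix(sites, cfg))
}

#' Apply the trio-level filters to candidate sites
#'
#' Evaluates filters 2-5 of the cascade: the Mendelian de novo pattern (both
#' parents HomRef, offspring Het), the offspring allelic-balance window
#' (inclusive bounds), the per-individual depth window relative to the mean
#' trio depth (strict bounds) and the genotype-quality floor. An offspring
#' with zero informative reads (AD ref + alt = 0) fails the allelic-balance
#' filter.
#'
#' @inheritParams apply_site_filters
#' @param m_depth mean depth of the trio (see [call_dnms()] for how it is
#'   derived from a full table).
#' @return A tibble with `passed` and `failed_filters` per site.
#' @export
apply_trio_filters <- function(sites, cfg = filter_config(), m_depth) {
  check_that(is.numeric(m_depth) && length(m_depth) == 1 && m_depth > 0,
             "`m_depth` must be a single positive number")
  failure_matrix_to_verdicts(trio_failure_matrix(sites, cfg, m_depth))
}

#' Call de novo mutations from a trio site table
#'
#' Runs the full five-filter cascade over an all-sites trio table and returns
#' the candidate de novo single-nucleotide mutations, together with an audit
#' trail counting, for each filter, how many Mendelian-violation sites it
#' removed. The mean trio depth used by the depth filter is the mean of the
#' three per-individual mean depths over the table. Multi-allelic records
#' (alternative allele longer than one base or containing a comma) are
#' skipped and counted in the audit. An optional exclusion list stands in
#' for an external cross-caller false-positive purge.
#'
#' @inheritParams apply_site_filters
#' @param trio_id label attached to the returned candidates; defaults to the
#'   table's `trio_id` column when present.
#' @param exclude optional data frame of `chrom`, `pos` to drop from the
#'   candidate list (external false-positive purge); removals are counted in
#'   the audit.
#' @return A tibble of candidates (`chrom`, `pos`, `ref`, `alt`, `trio_id`,
#'   `allele_balance`, `parent_of_origin` = "unphased", `context`) with
#'   attributes `audit` (per-filter loss counts among Mendelian-violation
#'   sites) and `m_depth`. Retrieve the audit with [dnm_audit()].
#' @export
call_dnms <- function(sites, cfg = filter_config(), trio_id = NULL,
                      exclude = NULL) {
  if (nrow(sites) == 0) {
    out <- candidate_tibble(sites[0, , drop = FALSE], character(0))
    attr(out, "audit") <- tibble(filter = character(0), n_removed = integer(0))
    attr(out, "m_depth") <- NA_real_
    return(out)
  }
  check_site_table(sites)
  if (is.null(trio_id)) {
    trio_id <- if ("trio_id" %in% names(sites)) sites$trio_id[1] else "trio"
  }

  multi <- !is.na(sites$alt) & (nchar(sites$alt) > 1 | grepl(",", sites$alt))
  biallelic <- sites[!multi, , drop = FALSE]

  m_depth <- mean(c(mean(biallelic$dp_father, na.rm = TRUE),
                    mean(biallelic$dp_mother, na.rm = TRUE),
                    mean(biallelic$dp_offspring, na.rm = TRUE)))

  fm_site <- site_failure_matrix(biallelic, cfg)
  fm_trio <- trio_failure_matrix(biallelic, cfg, m_depth)
  fm <- cbind(fm_site, fm_trio)
  pass <- rowSums(fm) == 0 & !is.na(biallelic$alt)

  # audit: losses among sites showing the de novo genotype pattern
  pattern <- !fm_trio[, "mendelian"]
  audit <- tibble(
    filter = colnames(fm),
    n_removed = as.integer(colSums(fm[pattern, , drop = FALSE]))
  )
  audit <- bind_rows(
    audit,
    tibble(filter = "multiallelic", n_removed = sum(multi))
  )

  cand <- candidate_tibble(biallelic[pass, , drop = FALSE], trio_id)
  if (!is.null(exclude) && nrow(cand) > 0) {
    drop <- paste(cand$chrom, cand$pos) %in% paste(exclude$chrom, exclude$pos)
    audit <- bind_rows(audit, tibble(filter = "external_exclusion",
                                     n_removed = sum(drop)))
    cand <- cand[!drop, , drop = FALSE]
  } else if (!is.null(exclude)) {
    audit <- bind_rows(audit, tibble(filter = "external_exclusion",
                                     n_removed = 0L))
  }
  attr(cand, "audit") <- audit
  attr(cand, "m_depth") <- m_depth
  cand
}

candidate_tibble <- function(rows, trio_id) {
  n_inf <- rows$ad_ref_offspring + rows$ad_alt_offspring
  tibble(
    chrom = rows$chrom,
    pos = rows$pos,
    ref = rows$ref,
    alt = rows$alt,
    trio_id = if (nrow(rows)) trio_id else character(0),
    allele_balance = ifelse(n_inf > 0, rows$ad_alt_offspring / n_inf,
                            NA_real_),
    parent_of_origin = if (nrow(rows)) "unphased" else character(0),
    context = if ("context" %in% names(rows)) rows$context
              else rep(NA_character_, nrow(rows))
  )
}

#' Retrieve the per-filter audit trail from a candidate table
#'
#' @param candidates the result of [call_dnms()].
#' @return A tibble with `filter` and `n_removed`.
#' @export
dnm_audit <- function(candidates) {
  audit <- attr(candidates, "audit")
  check_that(!is.null(audit), "no audit attached; was this made by call_dnms()?")
  audit
}
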