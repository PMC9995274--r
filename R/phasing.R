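#' Assign parent of origin to de novo mutations from linkage evidence
#'
#' Read-backed phasing at the level of informative linkage observations:
#' each observation records whether a read (pair) carrying — or not carrying —
#' the de novo allele also carried a particular allele of a nearby
#' heterozygous site, together with the parental genotypes at that site.
#' If the allele co-occurring with the de novo allele is carried by exactly
#' one parent, the observation votes for that parent; a read carrying the
#' other offspring haplotype votes for the opposite parent. Alleles present
#' in both parents (or neither) are uninformative. Any conflict among
#' informative observations leaves the mutation unphased: a false phase
#' biases the male-bias estimate more than a lost one.
#'
#' @param evidence a tibble with one row per observation: `dnm_id`,
#'   `read_id`, `linked_allele` (the base of the heterozygous site seen on
#'   the read), `dnm_allele_present` (logical: did this read carry the de
#'   novo allele), `father_gt`, `mother_gt` (genotypes at the linked site,
#'   e.g. `"A/C"`).
#' @return A tibble with one row per `dnm_id`: `parent_of_origin`
#'   (`"paternal"`, `"maternal"` or `"unphased"`), `n_obs`,
#'   `n_informative`, `conflicted`. Mutations with no observations are
#'   unphased, not errors.
#' @export
phase_dnms <- function(evidence) {
  needed <- c("dnm_id", "linked_allele", "dnm_allele_present",
              "father_gt", "mother_gt")
  check_that(all(needed %in% names(evidence)),
             paste0("evidence table needs columns: ",
                    paste(needed, collapse = ", ")))
  gt_has_allele <- function(gt, allele) {
    mapply(function(g, a) {
      if (is.na(g) || is.na(a)) return(NA)
      a %in% strsplit(g, "[/|]")[[1]]
    }, gt, allele, USE.NAMES = FALSE)
  }
  ev <- evidence |>
    mutate(
      in_father = gt_has_allele(.data$father_gt, .data$linked_allele),
      in_mother = gt_has_allele(.data$mother_gt, .data$linked_allele),
      informative = !is.na(.data$in_father) & !is.na(.data$in_mother) &
        xor(.data$in_father, .data$in_mother),
      # parent whose haplotype carries the de novo allele, per observation
      vote = case_when(
        !informative ~ NA_character_,
        .data$dnm_allele_present & .data$in_father ~ "paternal",
        .data$dnm_allele_present & .data$in_mother ~ "maternal",
        !.data$dnm_allele_present & .data$in_father ~ "maternal",
        TRUE ~ "paternal"
      )
    )
  ev |>
    group_by(.data$dnm_id) |>
    summarise(
      n_obs = n(),
      n_informative = sum(.data$informative),
      n_pat = sum(.data$vote == "paternal", na.rm = TRUE),
      n_mat = sum(.data$vote == "maternal", na.rm = TRUE),
      .groups = "drop"
    ) |>
    mutate(
      conflicted = .data$n_pat > 0 & .data$n_mat > 0,
      parent_of_origin = case_when(
        .data$conflicted ~ "unphased",
        .data$n_pat > 0 ~ "paternal",
        .data$n_mat > 0 ~ "maternal",
        TRUE ~ "unphased"
      )
    ) |>
    select("dnm_id", "parent_of_origin", "n_obs", "n_informative",
           "conflicted")
}

#' Male mutation bias (alpha) from phased counts
#'
#' Estimates the male-to-female ratio of germline mutation contributions,
#' `alpha = n_paternal / n_maternal`, per group. The confidence interval is
#' obtained by the monotone transform `p / (1 - p)` of the Wilson score
#' interval on the paternal fraction. Groups with fewer phased mutations
#' than `min_phased` are flagged low-confidence but still estimated; a group
#' with no maternal mutations yields an infinite alpha with a finite lower
#' bound.
#'
#' @param counts a tibble with columns `n_paternal` and `n_maternal`, and
#'   optionally a `group` column (species, order or class label).
#' @param conf confidence level.
#' @param min_phased minimum phased mutations for a confident estimate.
#' @return A tibble per group: `n_paternal`, `n_maternal`,
#'   `paternal_fraction`, `alpha`, `ci_low`, `ci_high`, `low_confidence`.
#' @examples
#' alpha_from_counts(tibble::tibble(n_paternal = 70, n_maternal = 30))
#' @export
alpha_from_counts <- function(counts, conf = 0.95, min_phased = 30) {
  check_that(all(c("n_paternal", "n_maternal") %in% names(counts)),
             "`counts` needs n_paternal and n_maternal columns")
  check_that(all(counts$n_paternal >= 0 & counts$n_maternal >= 0),
             "phased counts must be non-negative")
  n <- counts$n_paternal + counts$n_maternal
  check_that(all(n > 0), "at least one phased mutation is required per group")
  wi <- wilson_interval(counts$n_paternal, n, conf = conf)
  out <- counts |>
    mutate(
      paternal_fraction = .data$n_paternal / n,
      alpha = .data$n_paternal / .data$n_maternal,
      ci_low = wi$low / (1 - wi$low),
      ci_high = ifelse(wi$high < 1, wi$high / (1 - wi$high), Inf),
      low_confidence = n < min_phased
    )
  out
}

#' Fraction of de novo mutations shared between siblings
#'
#' In families where the same parent pair has two or more sequenced
#' offspring, a mutation observed at the identical position with the
#' identical alternative allele in two or more siblings is counted as
#' shared; such mutations arise before the parental germ lines separate
#' (primordial germ-cell specification). The fraction is shared mutation
#' instances over all mutation instances in multi-sibling families, with a
#' binomial standard error `sqrt(f (1 - f) / n)`.
#'
#' @param dnms a tibble of de novo mutations with columns `family_id`
#'   (parent pair), `trio_id` (offspring), `chrom`, `pos`, `alt`, and
#'   optionally a grouping column named by `by`.
#' @param by optional column name to stratify by (e.g. `"class"`).
#' @return A tibble (one row per stratum, or a single row): `n_instances`,
#'   `n_shared`, `shared_fraction`, `se`.
#' @export
sibling_sharing <- function(dnms, by = NULL) {
  needed <- c("family_id", "trio_id", "chrom", "pos", "alt")
  check_that(all(needed %in% names(dnms)),
             paste0("`dnms` needs columns: ", paste(needed, collapse = ", ")))
  fam_sizes <- dnms |>
    distinct(.data$family_id, .data$trio_id) |>
    count(.data$family_id, name = "n_sibs")
  multi <- fam_sizes$family_id[fam_sizes$n_sibs >= 2]
  check_that(length(multi) > 0,
             "no families with two or more sequenced siblings")
  d <- dnms |>
    filter(.data$family_id %in% multi) |>
    group_by(.data$family_id, .data$chrom, .data$pos, .data$alt) |>
    mutate(n_carriers = n_distinct(.data$trio_id)) |>
    ungroup() |>
    mutate(shared = .data$n_carriers >= 2)
  grouping <- if (is.null(by)) character(0) else by
  d |>
    group_by(across(all_of(grouping))) |>
    summarise(
      n_instances = n(),
      n_shared = sum(.data$shared),
      .groups = "drop"
    ) |>
    mutate(
      shared_fraction = .data$n_shared / .data$n_instances,
      se = sqrt(.data$shared_fraction * (1 - .data$shared_fraction) /
                  .data$n_instances)
    )
}
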