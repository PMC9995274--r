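#' Classify mutations into strand-collapsed classes
#'
#' Collapses each single-base substitution onto the A/C reference frame
#' (purine-origin mutations are complemented, and the trinucleotide context
#' reverse-complemented), yielding the six classes A>C, A>G, A>T, C>A, C>G,
#' C>T. Annotates transitions, CpG status (a C followed by G, or
#' equivalently a G preceded by C before collapsing) and the strong-to-weak
#' flag for C:G>T:A changes. Classification is invariant under
#' reverse-complementing ref, alt and context together.
#'
#' @param dnms a tibble with columns `ref`, `alt` (single bases) and
#'   optionally `context` (trinucleotide with the mutated base in the
#'   middle; `NA` when unknown).
#' @return The input with added columns `class`, `is_transition`, `is_cpg`
#'   (`NA` when the context of a C:G-origin mutation is unknown; `FALSE`
#'   for A:T-origin), `is_strong_to_weak`. Records with ambiguous bases are
#'   dropped with a warning; the dropped count is in attribute
#'   `n_ambiguous`.
#' @examples
#' classify_mutations(tibble::tibble(ref = "G", alt = "A", context = "CGT"))
#' @export
classify_mutations <- function(dnms) {
  check_that(all(c("ref", "alt") %in% names(dnms)),
             "`dnms` needs ref and alt columns")
  if (!"context" %in% names(dnms)) dnms$context <- NA_character_
  ok <- dnms$ref %in% BASES & dnms$alt %in% BASES & dnms$ref != dnms$alt
  n_ambiguous <- sum(!ok)
  if (n_ambiguous > 0) {
    warn(sprintf("%d records with ambiguous or invalid ref/alt dropped",
                 n_ambiguous))
  }
  d <- dnms[ok, , drop = FALSE]
  flip <- d$ref %in% c("G", "T")
  ref2 <- ifelse(flip, complement_base(d$ref), d$ref)
  alt2 <- ifelse(flip, complement_base(d$alt), d$alt)
  ctx2 <- d$context
  ctx2[flip] <- reverse_complement(d$context[flip])
  ctx_ok <- !is.na(ctx2) & nchar(ctx2) == 3
  next_base <- ifelse(ctx_ok, substr(ctx2, 3, 3), NA_character_)
  d$class <- paste0(ref2, ">", alt2)
  d$is_transition <- d$class %in% c("A>G", "C>T")
  d$is_cpg <- ifelse(ref2 == "C",
                     ifelse(is.na(next_base), NA, next_base == "G"),
                     FALSE)
  d$is_strong_to_weak <- d$class == "C>T"
  attr(d, "n_ambiguous") <- n_ambiguous
  d
}

MUTATION_CLASSES <- c("A>C", "A>G", "A>T", "C>A", "C>G", "C>T")

#' Build a mutation-spectrum contingency table
#'
#' Tabulates classified mutations into the six strand-collapsed classes by
#' group (typically the vertebrate classes: mammals, birds, fishes,
#' reptiles) and computes headline spectrum statistics with Wilson
#' confidence intervals: the transition/transversion ratio, the
#' strong-to-weak (C:G>T:A) proportion, and the CpG share among
#' strong-to-weak mutations. Mutations whose CpG status is unknown are
#' excluded from the CpG share, with their number reported.
#'
#' @param dnms a tibble as returned by [classify_mutations()], with a group
#'   column.
#' @param group name of the grouping column (default `"group"`).
#' @param conf confidence level for the Wilson intervals.
#' @return An object of class `gmr_spectrum`: a list with `counts` (tibble
#'   class x group), `matrix` (6 x n_groups integer matrix), `summary`
#'   (per-group and overall statistics). Supports [tidy()], [glance()] and
#'   [autoplot()].
#' @export
build_spectrum_table <- function(dnms, group = "group", conf = 0.95) {
  check_that(nrow(dnms) > 0, "empty mutation table")
  check_that(all(c("class", "is_transition", "is_cpg", "is_strong_to_weak")
                 %in% names(dnms)),
             "run classify_mutations() first")
  check_that(group %in% names(dnms),
             paste0("grouping column `", group, "` not found"))
  g <- as.character(dnms[[group]])
  check_that(!anyNA(g), "every mutation needs a group label")

  counts <- tibble(class = factor(dnms$class, levels = MUTATION_CLASSES),
                   group = g) |>
    count(.data$class, .data$group, .drop = FALSE, name = "n") |>
    mutate(class = as.character(.data$class))
  mat <- tapply(counts$n, list(counts$class, counts$group), sum)
  mat[is.na(mat)] <- 0
  mat <- mat[MUTATION_CLASSES, , drop = FALSE]
  storage.mode(mat) <- "integer"

  summarise_one <- function(d, label) {
    n <- nrow(d)
    n_ts <- sum(d$is_transition)
    n_sw <- sum(d$is_strong_to_weak)
    sw_ci <- wilson_interval(n_sw, n, conf)
    cpg_known <- d$is_strong_to_weak & !is.na(d$is_cpg)
    n_cpg_known <- sum(cpg_known)
    n_cpg <- sum(d$is_cpg[cpg_known])
    cpg_ci <- if (n_cpg_known > 0) wilson_interval(n_cpg, n_cpg_known, conf)
              else tibble(low = NA_real_, high = NA_real_)
    tibble(
      group = label, n_dnm = n,
      ts_tv = n_ts / (n - n_ts),
      strong_to_weak = n_sw / n,
      strong_to_weak_low = sw_ci$low, strong_to_weak_high = sw_ci$high,
      cpg_share_sw = if (n_cpg_known > 0) n_cpg / n_cpg_known else NA_real_,
      cpg_share_sw_low = cpg_ci$low, cpg_share_sw_high = cpg_ci$high,
      n_cpg_unknown = sum(d$is_strong_to_weak & is.na(d$is_cpg))
    )
  }
  dd <- tibble(class = dnms$class, group = g,
               is_transition = dnms$is_transition,
               is_cpg = dnms$is_cpg,
               is_strong_to_weak = dnms$is_strong_to_weak)
  summary <- bind_rows(
    summarise_one(dd, "overall"),
    dd |> group_by(.data$group) |> group_split() |>
      purrr::map(~ summarise_one(.x, .x$group[1])) |> bind_rows()
  )
  structure(list(counts = counts, matrix = mat, summary = summary),
            class = "gmr_spectrum")
}

#' @export
print.gmr_spectrum <- function(x, ...) {
  cat("Mutation spectrum:", sum(x$matrix), "mutations,",
      ncol(x$matrix), "groups\n")
  print(x$matrix)
  ov <- x$summary[x$summary$group == "overall", ]
  cat(sprintf("Ts/Tv = %.2f; strong-to-weak = %.1f%%; CpG share of C:G>T:A = %.1f%%\n",
              ov$ts_tv, 100 * ov$strong_to_weak, 100 * ov$cpg_share_sw))
  invisible(x)
}

#' @rdname build_spectrum_table
#' @param x,object a `gmr_spectrum` object.
#' @param ... unused.
#' @export
tidy.gmr_spectrum <- function(x, ...) x$counts

#' @rdname build_spectrum_table
#' @export
glance.gmr_spectrum <- function(x, ...) {
  x$summary[x$summary$group == "overall", ]
}

#' @rdname build_spectrum_table
#' @export
autoplot.gmr_spectrum <- function(object, ...) {
  d <- object$counts |>
    group_by(.data$group) |>
    mutate(prop = .data$n / sum(.data$n)) |>
    ungroup()
  ggplot2::ggplot(d, ggplot2::aes(x = .data$class, y = .data$prop,
                                  fill = .data$group)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = "mutation class (strand-collapsed)",
                  y = "proportion of de novo mutations", fill = NULL) +
    ggplot2::theme_minimal()
}

#' Pearson chi-squared test on a contingency table
#'
#' Independence test without continuity correction, as appropriate for the
#' spectrum-by-group tables whose counts are large.
#'
#' @param x a matrix of counts, a `gmr_spectrum` object, or a tibble of
#'   `class`, `group`, `n`.
#' @return A one-row tibble: `statistic`, `df`, `p_value`.
#' @export
chi_square_test <- function(x) {
  if (inherits(x, "gmr_spectrum")) x <- x$matrix
  if (is.data.frame(x)) {
    x <- tapply(x$n, list(x$class, x$group), sum)
  }
  x <- as.matrix(x)
  check_that(all(x >= 0), "counts must be non-negative")
  check_that(all(rowSums(x) > 0) && all(colSums(x) > 0),
             "every row and column must have a positive total")
  ct <- suppressWarnings(chisq.test(x, correct = FALSE))
  tibble(statistic = unname(ct$statistic),
         df = unname(ct$parameter),
         p_value = unname(ct$p.value))
}

#' Per-class contrast test
#'
#' Tests whether one mutation class is distributed differently across groups
#' than all remaining classes pooled: a 2 x n_groups Pearson chi-squared
#' test (class versus rest).
#'
#' @param spectrum a `gmr_spectrum` object or 6 x g count matrix.
#' @param class the mutation class to contrast, e.g. `"A>C"`.
#' @return A one-row tibble: `class`, `statistic`, `df`, `p_value`.
#' @export
class_contrast_test <- function(spectrum, class) {
  m <- if (inherits(spectrum, "gmr_spectrum")) spectrum$matrix
       else as.matrix(spectrum)
  check_that(class %in% rownames(m), "unknown mutation class")
  tab <- rbind(m[class, ], colSums(m) - m[class, ])
  out <- chi_square_test(tab)
  bind_cols(tibble(class = class), out)
}

#' One-way ANOVA of species rates across groups
#'
#' Compares species-level mean per-generation mutation rates among taxonomic
#' groups with a one-way analysis of variance.
#'
#' @param species_rates a tibble with one row per species containing the
#'   rate and group columns.
#' @param rate name of the rate column (default `"mu"`).
#' @param group name of the group column (default `"group"`).
#' @return A one-row tibble: `f_statistic`, `df_between`, `df_within`,
#'   `p_value`.
#' @export
class_anova <- function(species_rates, rate = "mu", group = "group") {
  check_that(all(c(rate, group) %in% names(species_rates)),
             "rate or group column not found")
  d <- tibble(y = species_rates[[rate]],
              g = factor(species_rates[[group]]))
  check_that(nlevels(d$g) >= 2, "at least two groups are required")
  check_that(nrow(d) > nlevels(d$g),
             "no within-group degrees of freedom")
  a <- anova(aov(y ~ g, data = d))
  tibble(
    f_statistic = a$`F value`[1],
    df_between = a$Df[1],
    df_within = a$Df[2],
    p_value = a$`Pr(>F)`[1]
  )
}
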