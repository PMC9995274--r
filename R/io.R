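#' Write a cohort to plain-text fixture files
#'
#' Emits the cohort as the file set the readers of this package (and common
#' external tools) consume: `trios.tsv`, `species.tsv`, `dnms.tsv`,
#' `tree.nwk` (Newick, branch lengths in Myr), `ne.tsv` (columns
#' `species`, `t_start_years`, `t_end_years`, `Ne`), and — when the cohort
#' carries site tables — one VCF v4.2 per trio plus `samples.tsv` mapping
#' trio ids to the father/mother/offspring sample columns, and `truth.tsv`
#' with the planted mutations. Positions are converted from the internal
#' 0-based convention to 1-based in the VCF.
#'
#' @param cohort a [simulate_cohort()] result.
#' @param dir output directory (created if needed).
#' @return Invisibly, the named character vector of files written.
#' @export
write_fixtures <- function(cohort, dir) {
  check_that(inherits(cohort, "gmr_cohort"), "`cohort` must be a gmr_cohort")
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  check_that(dir.exists(dir), paste0("cannot create directory ", dir))
  files <- c()
  p <- function(f) file.path(dir, f)

  readr::write_tsv(cohort$trios, p("trios.tsv"))
  readr::write_tsv(cohort$species, p("species.tsv"))
  readr::write_tsv(cohort$dnms, p("dnms.tsv"))
  ape::write.tree(cohort$tree, p("tree.nwk"))
  ne_out <- cohort$ne |>
    select("species", t_start_years = "t_start", t_end_years = "t_end",
           Ne = "ne")
  readr::write_tsv(ne_out, p("ne.tsv"))
  files <- c(trios = p("trios.tsv"), species = p("species.tsv"),
             dnms = p("dnms.tsv"), tree = p("tree.nwk"), ne = p("ne.tsv"))

  if (!is.null(cohort$sites)) {
    smap <- tibble(trio_id = names(cohort$sites),
                   father = "father", mother = "mother",
                   offspring = "offspring",
                   vcf = paste0(names(cohort$sites), ".vcf"))
    readr::write_tsv(smap, p("samples.tsv"))
    files <- c(files, samples = p("samples.tsv"))
    for (id in names(cohort$sites)) {
      write_trio_vcf(cohort$sites[[id]], p(paste0(id, ".vcf")))
    }
    if (!is.null(cohort$truth$planted)) {
      readr::write_tsv(cohort$truth$planted, p("truth.tsv"))
      files <- c(files, truth = p("truth.tsv"))
    }
  }
  invisible(files)
}

GT_TO_VCF <- c(HomRef = "0/0", Het = "0/1", HomAlt = "1/1", Missing = "./.")

#' Write one trio site table as VCF v4.2
#'
#' @param sites a trio site table (0-based `pos`; converted to 1-based).
#' @param path output file.
#' @param samples names for the three genotype columns, in father, mother,
#'   offspring order.
#' @return Invisibly, `path`.
#' @export
write_trio_vcf <- function(sites, path,
                           samples = c("father", "mother", "offspring")) {
  check_site_table(sites)
  num <- function(x) sprintf("%.9g", x)
  header <- c(
    "##fileformat=VCFv4.2",
    "##contig=<ID=chr1>",
    "##INFO=<ID=QD,Number=1,Type=Float,Description=\"QualByDepth\">",
    "##INFO=<ID=FS,Number=1,Type=Float,Description=\"FisherStrand\">",
    "##INFO=<ID=MQ,Number=1,Type=Float,Description=\"RMSMappingQuality\">",
    "##INFO=<ID=MQRankSum,Number=1,Type=Float,Description=\"MappingQualityRankSumTest\">",
    "##INFO=<ID=ReadPosRankSum,Number=1,Type=Float,Description=\"ReadPosRankSumTest\">",
    "##INFO=<ID=SOR,Number=1,Type=Float,Description=\"StrandOddsRatio\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allelic depths\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
    "##FORMAT=<ID=GQ,Number=1,Type=Integer,Description=\"Genotype quality\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t")
  )
  info <- paste0("QD=", num(sites$qd), ";FS=", num(sites$fs),
                 ";MQ=", num(sites$mq), ";MQRankSum=", num(sites$mq_rank_sum),
                 ";ReadPosRankSum=", num(sites$read_pos_rank_sum),
                 ";SOR=", num(sites$sor))
  fmt_sample <- function(who) {
    paste0(GT_TO_VCF[sites[[paste0("gt_", who)]]], ":",
           sites[[paste0("ad_ref_", who)]], ",",
           sites[[paste0("ad_alt_", who)]], ":",
           sites[[paste0("dp_", who)]], ":",
           sites[[paste0("gq_", who)]])
  }
  rows <- paste(sites$chrom, sites$pos + 1L, ".",
                sites$ref, ifelse(is.na(sites$alt), ".", sites$alt),
                ".", "PASS", info, "GT:AD:DP:GQ",
                fmt_sample("father"), fmt_sample("mother"),
                fmt_sample("offspring"),
                sep = "\t")
  writeLines(c(header, rows), path)
  invisible(path)
}

#' Read a trio VCF into a site table
#'
#' Parses a multi-sample VCF (via the vcfR package) into the internal trio
#' site table: 1-based positions become 0-based, genotypes are mapped to
#' HomRef/Het/HomAlt/Missing, and the GATK site annotations (QD, FS, MQ,
#' MQRankSum, ReadPosRankSum, SOR) are pulled from INFO, `NA` when absent.
#'
#' @param path VCF file.
#' @param father,mother,offspring sample column names in the VCF.
#' @param trio_id label for the trio; defaults to the file name.
#' @return A trio site table tibble.
#' @export
read_trio_vcf <- function(path, father = "father", mother = "mother",
                          offspring = "offspring", trio_id = NULL) {
  check_that(file.exists(path), paste0("no such file: ", path))
  if (is.null(trio_id)) trio_id <- sub("\\.vcf$", "", basename(path))
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  gt_raw <- vcfR::extract.gt(v, element = "GT")
  ad_raw <- vcfR::extract.gt(v, element = "AD")
  dp_raw <- vcfR::extract.gt(v, element = "DP", as.numeric = TRUE)
  gq_raw <- vcfR::extract.gt(v, element = "GQ", as.numeric = TRUE)
  for (s in c(father, mother, offspring)) {
    check_that(s %in% colnames(gt_raw),
               paste0("sample `", s, "` not found in ", path))
  }
  map_gt <- function(g) {
    dplyr::case_when(
      g %in% c("0/0", "0|0") ~ "HomRef",
      g %in% c("0/1", "1/0", "0|1", "1|0") ~ "Het",
      g %in% c("1/1", "1|1") ~ "HomAlt",
      TRUE ~ "Missing"
    )
  }
  ad_part <- function(x, i) {
    out <- suppressWarnings(as.integer(vapply(strsplit(x, ","), function(p)
      if (length(p) >= i) p[i] else NA_character_, character(1))))
    tidyr::replace_na(out, 0L)
  }
  info_num <- function(key) {
    suppressWarnings(as.numeric(vcfR::extract.info(v, element = key)))
  }
  tibble(
    trio_id = trio_id,
    chrom = fix[, "CHROM"],
    pos = as.integer(fix[, "POS"]) - 1L,
    ref = fix[, "REF"],
    alt = ifelse(fix[, "ALT"] %in% c(".", ""), NA_character_, fix[, "ALT"]),
    gt_father = map_gt(gt_raw[, father]),
    gt_mother = map_gt(gt_raw[, mother]),
    gt_offspring = map_gt(gt_raw[, offspring]),
    ad_ref_father = ad_part(ad_raw[, father], 1),
    ad_alt_father = ad_part(ad_raw[, father], 2),
    ad_ref_mother = ad_part(ad_raw[, mother], 1),
    ad_alt_mother = ad_part(ad_raw[, mother], 2),
    ad_ref_offspring = ad_part(ad_raw[, offspring], 1),
    ad_alt_offspring = ad_part(ad_raw[, offspring], 2),
    dp_father = as.integer(dp_raw[, father]),
    dp_mother = as.integer(dp_raw[, mother]),
    dp_offspring = as.integer(dp_raw[, offspring]),
    gq_father = as.integer(gq_raw[, father]),
    gq_mother = as.integer(gq_raw[, mother]),
    gq_offspring = as.integer(gq_raw[, offspring]),
    qd = info_num("QD"),
    fs = info_num("FS"),
    mq = info_num("MQ"),
    mq_rank_sum = info_num("MQRankSum"),
    read_pos_rank_sum = info_num("ReadPosRankSum"),
    sor = info_num("SOR")
  )
}

#' Read a piecewise-constant Ne trajectory
#'
#' Accepts the TSV convention `t_start_years`, `t_end_years`, `Ne`
#' (PSMC-style step function) or the internal `t_start`, `t_end`, `ne`
#' names, with an optional `species` column.
#'
#' @param path TSV file.
#' @return A tibble with `t_start`, `t_end`, `ne` (and `species` if
#'   present).
#' @export
read_ne_trajectory <- function(path) {
  check_that(file.exists(path), paste0("no such file: ", path))
  d <- readr::read_tsv(path, show_col_types = FALSE)
  nm <- names(d)
  if ("t_start_years" %in% nm) {
    d <- d |> rename(t_start = "t_start_years", t_end = "t_end_years",
                     ne = "Ne")
  }
  check_that(all(c("t_start", "t_end", "ne") %in% names(d)),
             "expected columns t_start(_years), t_end(_years), Ne")
  d
}
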