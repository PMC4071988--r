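#' Genotype counts for one study arm
#'
#' A triplet of genotype class counts for a biallelic SNP, always in the
#' order (homozygous common T1T1, heterozygous T1T2, homozygous variant
#' T2T2). The package never reorders or infers allele identity from
#' frequencies: the caller's column order is the contract.
#'
#' @param n11 Count of homozygous-common (T1T1) individuals.
#' @param n12 Count of heterozygous (T1T2) individuals.
#' @param n22 Count of homozygous-variant (T2T2) individuals.
#' @return An object of class `genotype_counts`.
#' @export
genotype_counts <- function(n11, n12, n22) {
  n <- c(n11 = n11, n12 = n12, n22 = n22)
  if (any(!is.finite(n)) || any(n < 0) || any(n != round(n)))
    stop("genotype counts must be non-negative integers", call. = FALSE)
  n <- as.integer(round(n))
  structure(list(n11 = n[1], n12 = n[2], n22 = n[3]),
            class = "genotype_counts")
}

#' @export
print.genotype_counts <- function(x, ...) {
  cat(sprintf("genotype counts: T1T1=%d T1T2=%d T2T2=%d (n=%d)\n",
              x$n11, x$n12, x$n22, x$n11 + x$n12 + x$n22))
  invisible(x)
}

#' Total number of individuals in a genotype-count arm
#' @param x A `genotype_counts` object.
#' @return Integer total.
#' @export
gc_total <- function(x) x$n11 + x$n12 + x$n22

.case_source_levels <- c("population_or_registry", "mixed", "hospital", "other")
.control_source_levels <- c("population", "volunteers_or_blood_bank",
                            "hospital_cancer_free", "not_described")
.specimen_levels <- c("blood_or_normal_tissue", "mixed_blood_paraffin",
                      "tumor_or_exfoliated")

.match_enum <- function(value, levels, aliases, field) {
  v <- tolower(trimws(as.character(value)))
  if (v %in% names(aliases)) v <- aliases[[v]]
  if (!v %in% levels)
    stop(sprintf("invalid %s '%s'; expected one of: %s",
                 field, value, paste(levels, collapse = ", ")), call. = FALSE)
  v
}

#' Study-quality features for the five-category rubric
#'
#' The rubric scores the source of cases, the source of controls, the
#' specimen type used for genotyping, Hardy-Weinberg equilibrium in
#' controls, and the total sample size. Tokens are matched
#' case-insensitively and a few common aliases are accepted
#' (e.g. "registry", "volunteers", "blood").
#'
#' @param case_source One of "population_or_registry", "mixed", "hospital",
#'   "other".
#' @param control_source One of "population", "volunteers_or_blood_bank",
#'   "hospital_cancer_free", "not_described".
#' @param specimen One of "blood_or_normal_tissue", "mixed_blood_paraffin",
#'   "tumor_or_exfoliated".
#' @param hwe_in_controls Logical: are control genotypes in Hardy-Weinberg
#'   equilibrium?
#' @param total_sample_size Integer, cases plus controls.
#' @return An object of class `quality_features`.
#' @export
quality_features <- function(case_source, control_source, specimen,
                             hwe_in_controls, total_sample_size) {
  cs <- .match_enum(case_source, .case_source_levels,
                    c(registry = "population_or_registry",
                      population = "population_or_registry",
                      cancer_registry = "population_or_registry"),
                    "case_source")
  ctl <- .match_enum(control_source, .control_source_levels,
                     c(volunteers = "volunteers_or_blood_bank",
                       blood_bank = "volunteers_or_blood_bank",
                       hospital = "hospital_cancer_free"),
                     "control_source")
  sp <- .match_enum(specimen, .specimen_levels,
                    c(blood = "blood_or_normal_tissue",
                      normal_tissue = "blood_or_normal_tissue",
                      mixed = "mixed_blood_paraffin",
                      tumor = "tumor_or_exfoliated"),
                    "specimen")
  if (is.na(hwe_in_controls) || !is.logical(hwe_in_controls))
    stop("hwe_in_controls must be TRUE or FALSE", call. = FALSE)
  n <- as.integer(total_sample_size)
  if (is.na(n) || n < 0)
    stop("total_sample_size must be a non-negative integer", call. = FALSE)
  structure(list(case_source = cs, control_source = ctl, specimen = sp,
                 hwe_in_controls = hwe_in_controls, total_sample_size = n),
            class = "quality_features")
}

#' One case-control study
#'
#' @param study_id Short unique label, typically the first author.
#' @param year Publication year.
#' @param cases,controls `genotype_counts` for each arm.
#' @param metadata Optional `quality_features` for rubric scoring.
#' @return An object of class `study_record`.
#' @export
study_record <- function(study_id, year, cases, controls, metadata = NULL) {
  stopifnot(inherits(cases, "genotype_counts"),
            inherits(controls, "genotype_counts"))
  if (!is.null(metadata) && !inherits(metadata, "quality_features"))
    stop("metadata must be a quality_features object or NULL", call. = FALSE)
  structure(list(study_id = as.character(study_id), year = as.integer(year),
                 cases = cases, controls = controls, metadata = metadata),
            class = "study_record")
}

#' A dataset of studies for one SNP
#'
#' Study order is preserved for reporting but never affects any numeric
#' result.
#'
#' @param snp_id SNP identifier (e.g. an rs number).
#' @param studies List of `study_record` objects.
#' @return An object of class `snp_dataset`.
#' @export
snp_dataset <- function(snp_id, studies) {
  stopifnot(is.list(studies))
  for (s in studies) stopifnot(inherits(s, "study_record"))
  structure(list(snp_id = as.character(snp_id), studies = studies),
            class = "snp_dataset")
}

#' @export
print.snp_dataset <- function(x, ...) {
  cat(sprintf("snp_dataset '%s': %d studies\n", x$snp_id, length(x$studies)))
  for (s in x$studies)
    cat(sprintf("  %s (%d): cases %d/%d/%d, controls %d/%d/%d\n",
                s$study_id, s$year,
                s$cases$n11, s$cases$n12, s$cases$n22,
                s$controls$n11, s$controls$n12, s$controls$n22))
  invisible(x)
}

#' @export
length.snp_dataset <- function(x) length(x$studies)

.count_cols <- c("case_11", "case_12", "case_22",
                 "ctrl_11", "ctrl_12", "ctrl_22")
.meta_cols <- c("case_source", "control_source", "specimen",
                "hwe_in_controls", "total_sample_size")

#' Read a per-study genotype-count table from CSV
#'
#' Expects a header with columns `study_id`, `year`, `case_11`, `case_12`,
#' `case_22`, `ctrl_11`, `ctrl_12`, `ctrl_22`; the metadata columns
#' `case_source`, `control_source`, `specimen`, `hwe_in_controls`,
#' `total_sample_size` are optional and, when all present, populate
#' `quality_features`. Lines starting with `#` are ignored.
#'
#' @param path Path to the CSV (or TSV, with `sep = "\t"`) file.
#' @param snp_id SNP identifier to attach to the dataset.
#' @param sep Field separator; comma by default.
#' @return A `snp_dataset`.
#' @export
read_study_table <- function(path, snp_id, sep = ",") {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, comment.char = "#")
  required <- c("study_id", "year", .count_cols)
  missing <- setdiff(required, names(df))
  if (length(missing) > 0)
    stop(sprintf("missing required column(s): %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  for (col in .count_cols) {
    v <- suppressWarnings(as.numeric(df[[col]]))
    bad <- which(!is.finite(v) | v < 0 | v != round(v))
    if (length(bad) > 0)
      stop(sprintf("column %s: invalid count in row %d (must be a non-negative integer)",
                   col, bad[1]), call. = FALSE)
  }
  dup <- df$study_id[duplicated(df$study_id)]
  if (length(dup) > 0)
    stop(sprintf("duplicate study_id: %s", paste(unique(dup), collapse = ", ")),
         call. = FALSE)
  has_meta <- all(.meta_cols %in% names(df))
  studies <- lapply(seq_len(nrow(df)), function(i) {
    r <- df[i, ]
    meta <- NULL
    if (has_meta)
      meta <- quality_features(r$case_source, r$control_source, r$specimen,
                               as.logical(r$hwe_in_controls),
                               r$total_sample_size)
    study_record(r$study_id, r$year,
                 genotype_counts(r$case_11, r$case_12, r$case_22),
                 genotype_counts(r$ctrl_11, r$ctrl_12, r$ctrl_22),
                 metadata = meta)
  })
  snp_dataset(snp_id, studies)
}

#' Write a dataset back to the CSV schema read by [read_study_table()]
#'
#' @param ds A `snp_dataset`.
#' @param path Output path.
#' @param sep Field separator.
#' @return `path`, invisibly.
#' @export
write_study_table <- function(ds, path, sep = ",") {
  stopifnot(inherits(ds, "snp_dataset"))
  rows <- lapply(ds$studies, function(s) {
    base <- data.frame(study_id = s$study_id, year = s$year,
                       case_11 = s$cases$n11, case_12 = s$cases$n12,
                       case_22 = s$cases$n22,
                       ctrl_11 = s$controls$n11, ctrl_12 = s$controls$n12,
                       ctrl_22 = s$controls$n22,
                       stringsAsFactors = FALSE)
    if (!is.null(s$metadata)) {
      m <- s$metadata
      base$case_source <- m$case_source
      base$control_source <- m$control_source
      base$specimen <- m$specimen
      base$hwe_in_controls <- m$hwe_in_controls
      base$total_sample_size <- m$total_sample_size
    }
    base
  })
  df <- do.call(rbind, rows)
  utils::write.table(df, path, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Load a packaged genotype-count fixture
#'
#' The package ships the genotype tables of a published XRCC3
#' ovarian-cancer meta-analysis: rs861539 (4 studies), rs1799794
#' (2 studies) and rs1799796 (2 studies), each with study metadata for
#' quality scoring.
#'
#' @param snp_id One of "rs861539", "rs1799794", "rs1799796".
#' @return A `snp_dataset`.
#' @export
load_fixture <- function(snp_id) {
  valid <- c("rs861539", "rs1799794", "rs1799796")
  if (!snp_id %in% valid)
    stop(sprintf("unknown fixture '%s'; valid ids: %s",
                 snp_id, paste(valid, collapse = ", ")), call. = FALSE)
  path <- system.file("extdata", paste0(snp_id, ".csv"), package = "snpmeta",
                      mustWork = TRUE)
  read_study_table(path, snp_id)
}

#' Validate a dataset, returning findings instead of raising
#'
#' @param ds A `snp_dataset`.
#' @return A data frame with columns `study_id`, `field`, `message`; zero
#'   rows when all invariants hold.
#' @export
validate_dataset <- function(ds) {
  findings <- list()
  add <- function(study_id, field, message)
    findings[[length(findings) + 1]] <<- data.frame(
      study_id = study_id, field = field, message = message,
      stringsAsFactors = FALSE)
  if (!inherits(ds, "snp_dataset")) {
    add(NA_character_, "dataset", "not a snp_dataset")
  } else {
    if (length(ds$studies) == 0)
      add(NA_character_, "studies", "no studies")
    ids <- vapply(ds$studies, function(s) s$study_id, character(1))
    for (d in unique(ids[duplicated(ids)]))
      add(d, "study_id", "duplicate study_id")
    for (s in ds$studies) {
      if (gc_total(s$cases) == 0)
        add(s$study_id, "cases", "empty arm")
      if (gc_total(s$controls) == 0)
        add(s$study_id, "controls", "empty arm")
    }
  }
  if (length(findings) == 0)
    data.frame(study_id = character(), field = character(),
               message = character(), stringsAsFactors = FALSE)
  else
    do.call(rbind, findings)
}

#' Main characteristics of the packaged studies
#'
#' The per-article study characteristics of the packaged meta-analysis:
#' overall case and control counts, rubric features, and the quality
#' score as printed in the source publication. The `cases`/`controls`
#' columns are the per-article totals (the largest genotyped subset),
#' which can exceed the per-SNP genotype sums in [load_fixture()]
#' datasets.
#'
#' @return A data frame, one row per article.
#' @export
study_characteristics <- function() {
  path <- system.file("extdata", "study_characteristics.csv",
                      package = "snpmeta", mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Printed odds-ratio cells of the source tables
#'
#' Returns the per-study and pooled OR/CI/p cells as printed in the source
#' meta-analysis (2-decimal values), used by [reproduce_printed()] to diff
#' recomputed results against the publication.
#'
#' @return A data frame with columns `snp_id`, `study_id` ("Total" for
#'   pooled rows), `model`, `or`, `ci_low`, `ci_high`, `p`.
#' @export
printed_results <- function() {
  path <- system.file("extdata", "printed_results.csv", package = "snpmeta",
                      mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}
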