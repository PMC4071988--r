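#' The four genetic-model contrasts
#'
#' @return Character vector: "homozygote", "heterozygote", "dominant",
#'   "recessive".
#' @export
genetic_models <- function()
  c("homozygote", "heterozygote", "dominant", "recessive")

#' A 2x2 exposure-by-disease table
#'
#' Cell layout follows the epidemiological convention: `a` exposed cases,
#' `b` unexposed cases, `c` exposed controls, `d` unexposed controls.
#' Counts are integers on construction; continuity correction may later
#' make them half-integral.
#'
#' @param a,b,c,d Non-negative cell counts.
#' @return An object of class `two_by_two`.
#' @export
two_by_two <- function(a, b, c, d) {
  cells <- c(a = a, b = b, c = c, d = d)
  if (any(!is.finite(cells)) || any(cells < 0))
    stop("2x2 cells must be non-negative", call. = FALSE)
  # doubles, not integers: cross-products of large cohorts overflow
  # 32-bit integer arithmetic
  cells <- as.numeric(cells)
  structure(list(a = cells[1], b = cells[2], c = cells[3], d = cells[4]),
            class = "two_by_two")
}

#' Build the 2x2 table for a genetic-model contrast
#'
#' The four contrasts compare, against the homozygous-common genotype
#' unless stated otherwise: homozygote (T2T2 vs T1T1), heterozygote
#' (T1T2 vs T1T1), dominant (T1T2+T2T2 vs T1T1), and recessive
#' (T2T2 vs T1T1+T1T2). Rows of the resulting table are case/control;
#' columns are the contrast's "exposed"/"unexposed" genotype groups.
#'
#' @param study A `study_record`.
#' @param model One of [genetic_models()].
#' @return A `two_by_two` table.
#' @export
build_contrast <- function(study, model) {
  stopifnot(inherits(study, "study_record"))
  model <- match.arg(model, genetic_models())
  ca <- study$cases; ct <- study$controls
  switch(model,
    homozygote   = two_by_two(ca$n22, ca$n11, ct$n22, ct$n11),
    heterozygote = two_by_two(ca$n12, ca$n11, ct$n12, ct$n11),
    dominant     = two_by_two(ca$n12 + ca$n22, ca$n11,
                              ct$n12 + ct$n22, ct$n11),
    recessive    = two_by_two(ca$n22, ca$n11 + ca$n12,
                              ct$n22, ct$n11 + ct$n12))
}

# z for 95% Wald intervals; full-precision quantile, not 1.96
.z975 <- stats::qnorm(0.975)

.apply_cc <- function(t, cc) {
  cells <- c(t$a, t$b, t$c, t$d)
  corrected <- FALSE
  if (cc == "halves-always" || (cc == "halves-when-zero" && any(cells == 0))) {
    cells <- cells + 0.5
    corrected <- TRUE
  }
  list(cells = cells, corrected = corrected)
}

#' Odds ratio with Wald confidence interval for a 2x2 table
#'
#' The odds ratio is the cross-product ratio (a*d)/(b*c); the standard
#' error of its log is sqrt(1/a + 1/b + 1/c + 1/d) (Woolf), the CI is the
#' 95% Wald interval on the log scale, and the p-value is the two-sided
#' normal test of log(OR)/SE.
#'
#' @param t A `two_by_two` table.
#' @param cc Continuity-correction policy: "halves-when-zero" (default,
#'   add 0.5 to all four cells only when some cell is zero), "none", or
#'   "halves-always".
#' @return An object of class `effect_estimate` with fields `log_or`, `se`,
#'   `or`, `ci_low`, `ci_high`, `p_value`, `corrected`.
#' @export
odds_ratio <- function(t, cc = c("halves-when-zero", "none", "halves-always")) {
  stopifnot(inherits(t, "two_by_two"))
  cc <- match.arg(cc)
  if ((t$a + t$c) == 0 || (t$b + t$d) == 0 || (t$a + t$b) == 0 ||
      (t$c + t$d) == 0)
    stop("undefined effect: an entire table margin is empty", call. = FALSE)
  x <- .apply_cc(t, cc)
  if (any(x$cells == 0))
    stop(paste("degenerate table: zero cell with no continuity correction;",
               "use cc = 'halves-when-zero' or 'halves-always'"),
         call. = FALSE)
  a <- x$cells[1]; b <- x$cells[2]; c <- x$cells[3]; d <- x$cells[4]
  log_or <- log((a * d) / (b * c))
  se <- sqrt(1 / a + 1 / b + 1 / c + 1 / d)
  effect_estimate(log_or, se, corrected = x$corrected)
}

#' Construct an effect estimate from a log odds ratio and its SE
#'
#' @param log_or Natural-log odds ratio.
#' @param se Standard error of `log_or` (> 0).
#' @param corrected Whether a continuity correction was applied upstream.
#' @return An object of class `effect_estimate`.
#' @export
effect_estimate <- function(log_or, se, corrected = FALSE) {
  stopifnot(is.finite(log_or), is.finite(se), se > 0)
  z <- log_or / se
  structure(list(
    log_or = log_or, se = se, or = exp(log_or),
    ci_low = exp(log_or - .z975 * se),
    ci_high = exp(log_or + .z975 * se),
    p_value = 2 * stats::pnorm(-abs(z)),
    corrected = corrected), class = "effect_estimate")
}

#' @export
print.effect_estimate <- function(x, ...) {
  cat(sprintf("OR %.2f [%.2f, %.2f], p = %.4g%s\n", x$or, x$ci_low,
              x$ci_high, x$p_value,
              if (x$corrected) " (continuity-corrected)" else ""))
  invisible(x)
}

#' Hardy-Weinberg equilibrium test for a genotype-count arm
#'
#' Pearson chi-square (1 df, no continuity correction) of the observed
#' genotype counts against the expectations ((1-q)^2, 2q(1-q), q^2) * n
#' implied by the sample allele frequency q. A monomorphic sample (one
#' allele absent) is returned as in equilibrium with chi-square 0 and
#' `monomorphic = TRUE` rather than an error.
#'
#' @param controls A `genotype_counts` arm (conventionally controls).
#' @param alpha Significance level for the `in_equilibrium` flag.
#' @return An object of class `hwe_result` with `chi_square`, `df`,
#'   `p_value`, `in_equilibrium`, `monomorphic`.
#' @export
hwe_test <- function(controls, alpha = 0.05) {
  stopifnot(inherits(controls, "genotype_counts"))
  n <- gc_total(controls)
  if (n < 1) stop("at least one individual required", call. = FALSE)
  q <- (2 * controls$n22 + controls$n12) / (2 * n)  # variant allele freq
  if (q == 0 || q == 1) {
    warning("monomorphic sample: Hardy-Weinberg test is vacuous")
    return(structure(list(chi_square = 0, df = 1L, p_value = 1,
                          in_equilibrium = TRUE, monomorphic = TRUE),
                     class = "hwe_result"))
  }
  expected <- n * c((1 - q)^2, 2 * q * (1 - q), q^2)
  observed <- c(controls$n11, controls$n12, controls$n22)
  chi <- sum((observed - expected)^2 / expected)
  p <- stats::pchisq(chi, df = 1, lower.tail = FALSE)
  structure(list(chi_square = chi, df = 1L, p_value = p,
                 in_equilibrium = p > alpha, monomorphic = FALSE),
            class = "hwe_result")
}

# Rubric point scales, keyed by the quality_features enum tokens.
.case_source_points <- c(population_or_registry = 3, mixed = 2,
                         hospital = 1, other = 0)
.control_source_points <- c(population = 3, volunteers_or_blood_bank = 2,
                            hospital_cancer_free = 1, not_described = 0)
.specimen_points <- c(blood_or_normal_tissue = 3, mixed_blood_paraffin = 1,
                      tumor_or_exfoliated = 0)

.size_points <- function(n) {
  if (n >= 1000) 3L else if (n >= 500) 2L else if (n >= 200) 1L else 0L
}

#' Score a study on the five-category quality rubric
#'
#' Points: source of cases (population/registry 3, mixed 2, hospital 1,
#' other 0); source of controls (population 3, volunteers/blood bank 2,
#' cancer-free hospital patients 1, not described 0); genotyping specimen
#' (blood or normal tissue 3, mixed blood/paraffin 1, tumor or exfoliated
#' cells 0); Hardy-Weinberg equilibrium in controls (yes 3, no 0); total
#' sample size (>=1000: 3, 500-999: 2, 200-499: 1, <200: 0). Totals range
#' 0-15; studies scoring >= 10 are flagged high quality.
#'
#' @param f A `quality_features` object.
#' @return An object of class `quality_score` with `total`,
#'   `per_category` (named numeric of five sub-scores), `is_high_quality`.
#' @export
quality_score <- function(f) {
  stopifnot(inherits(f, "quality_features"))
  per <- c(case_source = unname(.case_source_points[f$case_source]),
           control_source = unname(.control_source_points[f$control_source]),
           specimen = unname(.specimen_points[f$specimen]),
           hwe = if (f$hwe_in_controls) 3 else 0,
           sample_size = .size_points(f$total_sample_size))
  total <- as.integer(sum(per))
  structure(list(total = total, per_category = per,
                 is_high_quality = total >= 10L),
            class = "quality_score")
}
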