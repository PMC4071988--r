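#' Parameters for the case-control genotype simulator
#'
#' Controls are drawn multinomially from Hardy-Weinberg proportions at
#' variant allele frequency `q`; cases from the same proportions tilted by
#' per-genotype odds ratios (`or_het` for heterozygotes, `or_hom` for
#' variant homozygotes, both relative to the common homozygote).
#' Between-study heterogeneity, when `tau > 0`, adds a per-study
#' Normal(0, tau^2) shift to both log odds ratios before normalization.
#'
#' @param q Variant (T2) allele frequency in controls, in (0, 1).
#' @param or_het True heterozygote odds ratio (> 0).
#' @param or_hom True variant-homozygote odds ratio (> 0).
#' @param n_cases,n_controls Arm sizes per study (>= 1).
#' @param k Number of studies (>= 1).
#' @param tau Between-study SD of the log odds ratio (>= 0).
#' @param seed Integer master seed; per-study substreams are derived from
#'   it so each study is reproducible independently of generation order.
#' @return An object of class `sim_params`.
#' @export
sim_params <- function(q, or_het = 1, or_hom = 1, n_cases = 1000,
                       n_controls = 1000, k = 1, tau = 0, seed = 1) {
  if (!is.finite(q) || q <= 0 || q >= 1)
    stop("q must lie strictly between 0 and 1", call. = FALSE)
  if (or_het <= 0 || or_hom <= 0)
    stop("odds ratios must be positive", call. = FALSE)
  if (n_cases < 0 || n_controls < 0)
    stop("arm sizes must be non-negative", call. = FALSE)
  if (k < 1) stop("k must be at least 1", call. = FALSE)
  if (tau < 0) stop("tau must be non-negative", call. = FALSE)
  structure(list(q = q, or_het = or_het, or_hom = or_hom,
                 n_cases = as.integer(n_cases),
                 n_controls = as.integer(n_controls),
                 k = as.integer(k), tau = tau, seed = as.integer(seed)),
            class = "sim_params")
}

#' Expected genotype probabilities in controls and cases
#'
#' Controls follow Hardy-Weinberg: ((1-q)^2, 2q(1-q), q^2). Case
#' probabilities are the control probabilities multiplied by
#' (1, or_het, or_hom) and renormalized, so the sample odds ratio of each
#' genotype class against the common homozygote converges to the supplied
#' parameter.
#'
#' @param q Variant allele frequency in (0, 1).
#' @param or_het,or_hom Per-genotype odds ratios (> 0).
#' @return List with numeric 3-vectors `controls` and `cases`, ordered
#'   (T1T1, T1T2, T2T2).
#' @export
expected_genotype_probs <- function(q, or_het = 1, or_hom = 1) {
  if (!is.finite(q) || q <= 0 || q >= 1)
    stop("q must lie strictly between 0 and 1", call. = FALSE)
  if (or_het <= 0 || or_hom <= 0)
    stop("odds ratios must be positive", call. = FALSE)
  ctrl <- c((1 - q)^2, 2 * q * (1 - q), q^2)
  case <- ctrl * c(1, or_het, or_hom)
  list(controls = ctrl, cases = case / sum(case))
}

# Substream seed for study i: a fixed affine counter map of the master
# seed, reduced mod 2^31 - 1 so it stays a valid 32-bit integer.
.substream_seed <- function(seed, study_index) {
  as.integer((as.double(seed) + 1000003 * as.double(study_index)) %% 2147483647)
}

#' Simulate one case-control study
#'
#' Deterministic given (`p$seed`, `study_index`): the study's substream
#' seed is derived by a counter scheme, so regenerating any single study
#' gives identical counts regardless of the order studies are drawn in.
#'
#' @param p A `sim_params` object.
#' @param study_index 1-based study index within the dataset.
#' @return A `study_record` named `sim<study_index>`.
#' @export
simulate_study <- function(p, study_index = 1) {
  stopifnot(inherits(p, "sim_params"))
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(.substream_seed(p$seed, study_index))
  shift <- if (p$tau > 0) stats::rnorm(1, 0, p$tau) else 0
  probs <- expected_genotype_probs(p$q, exp(log(p$or_het) + shift),
                                   exp(log(p$or_hom) + shift))
  draw <- function(n, pr) {
    if (n == 0) return(c(0L, 0L, 0L))
    as.integer(stats::rmultinom(1, n, pr))
  }
  ctrl <- draw(p$n_controls, probs$controls)
  case <- draw(p$n_cases, probs$cases)
  study_record(paste0("sim", study_index), 0L,
               genotype_counts(case[1], case[2], case[3]),
               genotype_counts(ctrl[1], ctrl[2], ctrl[3]))
}

#' Simulate a full dataset of k studies
#'
#' @param p A `sim_params` object.
#' @return A `snp_dataset` whose `snp_id` records the generating
#'   parameters.
#' @export
simulate_dataset <- function(p) {
  stopifnot(inherits(p, "sim_params"))
  studies <- lapply(seq_len(p$k), function(i) simulate_study(p, i))
  snp_id <- sprintf("sim(q=%g,or_het=%g,or_hom=%g,tau=%g,seed=%d)",
                    p$q, p$or_het, p$or_hom, p$tau, p$seed)
  snp_dataset(snp_id, studies)
}
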