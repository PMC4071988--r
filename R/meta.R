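#' Configuration for a meta-analysis run
#'
#' @param heterogeneity_alpha Threshold below which the Cochran Q p-value
#'   marks heterogeneity as significant (then random effects are selected).
#' @param fixed_method Fixed-effects estimator: "mh" (Mantel-Haenszel,
#'   default) or "iv" (inverse variance).
#' @param cc Continuity-correction policy passed to [odds_ratio()].
#' @param hwe_alpha Significance level for [hwe_test()].
#' @return An object of class `meta_config`.
#' @export
meta_config <- function(heterogeneity_alpha = 0.05,
                        fixed_method = c("mh", "iv"),
                        cc = "halves-when-zero",
                        hwe_alpha = 0.05) {
  fixed_method <- match.arg(fixed_method)
  stopifnot(heterogeneity_alpha > 0, heterogeneity_alpha < 1,
            hwe_alpha > 0, hwe_alpha < 1)
  structure(list(heterogeneity_alpha = heterogeneity_alpha,
                 fixed_method = fixed_method, cc = cc,
                 hwe_alpha = hwe_alpha), class = "meta_config")
}

.check_effects <- function(effects, k_min = 2) {
  stopifnot(is.list(effects))
  if (length(effects) < k_min)
    stop(sprintf("at least %d studies required, got %d",
                 k_min, length(effects)), call. = FALSE)
  for (e in effects) stopifnot(inherits(e, "effect_estimate"))
  invisible(effects)
}

#' Cochran's Q heterogeneity test with I-squared and DL tau-squared
#'
#' Q is the inverse-variance weighted sum of squared deviations of the
#' per-study log odds ratios about the IV fixed-effects pooled estimate,
#' referred to a chi-square with k-1 degrees of freedom.
#' I^2 = max(0, (Q - df)/Q); tau^2 is the DerSimonian-Laird moment
#' estimator max(0, (Q - df) / (sum(w) - sum(w^2)/sum(w))).
#'
#' @param effects List of `effect_estimate` objects (k >= 2).
#' @return An object of class `heterogeneity_result` with `q`, `df`,
#'   `p_value`, `i_squared`, `tau_squared`.
#' @export
cochran_q <- function(effects) {
  .check_effects(effects, 2)
  theta <- vapply(effects, function(e) e$log_or, numeric(1))
  w <- vapply(effects, function(e) 1 / e$se^2, numeric(1))
  pooled <- sum(w * theta) / sum(w)
  q <- sum(w * (theta - pooled)^2)
  df <- length(effects) - 1L
  p <- stats::pchisq(q, df = df, lower.tail = FALSE)
  i2 <- if (q > 0) max(0, (q - df) / q) else 0
  denom <- sum(w) - sum(w^2) / sum(w)
  tau2 <- if (denom > 0) max(0, (q - df) / denom) else 0
  structure(list(q = q, df = df, p_value = p, i_squared = i2,
                 tau_squared = tau2), class = "heterogeneity_result")
}

.pooled_result <- function(method, log_or, se, het, k, model = NA_character_,
                           selected = FALSE) {
  structure(list(model = model, method = method,
                 estimate = effect_estimate(log_or, se),
                 heterogeneity = het, k = k, selected = selected),
            class = "pooled_result")
}

#' @export
print.pooled_result <- function(x, ...) {
  e <- x$estimate
  cat(sprintf("%s pooled (k=%d, %s): OR %.2f [%.2f, %.2f], p = %.4g\n",
              if (is.na(x$model)) "" else x$model, x$k, x$method,
              e$or, e$ci_low, e$ci_high, e$p_value))
  if (!is.null(x$heterogeneity))
    cat(sprintf("  heterogeneity: Q = %.3f (df %d), p = %.3f, I2 = %.1f%%, tau2 = %.4f\n",
                x$heterogeneity$q, x$heterogeneity$df,
                x$heterogeneity$p_value, 100 * x$heterogeneity$i_squared,
                x$heterogeneity$tau_squared))
  invisible(x)
}

#' Mantel-Haenszel fixed-effects pooling of 2x2 tables
#'
#' Pooled OR = sum(a_i d_i / n_i) / sum(b_i c_i / n_i). The standard error
#' of the pooled log OR is the Robins-Breslow-Greenland variance:
#' with P_i = (a_i+d_i)/n_i, Q_i = (b_i+c_i)/n_i, R_i = a_i d_i / n_i,
#' S_i = b_i c_i / n_i, R = sum(R_i), S = sum(S_i),
#' Var = sum(P_i R_i)/(2 R^2) + sum(P_i S_i + Q_i R_i)/(2 R S)
#'     + sum(Q_i S_i)/(2 S^2).
#' Tables are pooled on their raw counts (no continuity correction);
#' stratified pooling tolerates zero cells as long as both cross-product
#' sums are positive.
#'
#' @param tables List of `two_by_two` tables (k >= 2).
#' @param het Optional precomputed `heterogeneity_result` to attach; by
#'   default Q is computed from the per-table Woolf effects.
#' @return A `pooled_result` with method "mantel_haenszel_fixed".
#' @export
pool_mantel_haenszel <- function(tables, het = NULL) {
  stopifnot(is.list(tables))
  if (length(tables) < 2)
    stop(sprintf("at least 2 studies required, got %d", length(tables)),
         call. = FALSE)
  for (t in tables) stopifnot(inherits(t, "two_by_two"))
  a <- vapply(tables, `[[`, numeric(1), "a")
  b <- vapply(tables, `[[`, numeric(1), "b")
  c_ <- vapply(tables, `[[`, numeric(1), "c")
  d <- vapply(tables, `[[`, numeric(1), "d")
  n <- a + b + c_ + d
  if (any(n == 0)) stop("a table has total 0", call. = FALSE)
  R_i <- a * d / n; S_i <- b * c_ / n
  R <- sum(R_i); S <- sum(S_i)
  if (S == 0 || R == 0)
    stop("undefined effect: a Mantel-Haenszel cross-product sum is zero",
         call. = FALSE)
  P_i <- (a + d) / n; Q_i <- (b + c_) / n
  log_or <- log(R / S)
  var_log <- sum(P_i * R_i) / (2 * R^2) +
    sum(P_i * S_i + Q_i * R_i) / (2 * R * S) +
    sum(Q_i * S_i) / (2 * S^2)
  if (is.null(het))
    het <- cochran_q(lapply(tables, odds_ratio))
  .pooled_result("mantel_haenszel_fixed", log_or, sqrt(var_log), het,
                 length(tables))
}

#' Inverse-variance pooling, fixed or DerSimonian-Laird random effects
#'
#' Fixed effects weight each study by 1/se^2; random effects by
#' 1/(se^2 + tau^2) with the DerSimonian-Laird moment tau^2 from
#' [cochran_q()]. The pooled log OR is the weighted mean, its SE
#' 1/sqrt(sum of weights).
#'
#' @param effects List of `effect_estimate` objects (k >= 2).
#' @param random If TRUE, DerSimonian-Laird random effects.
#' @return A `pooled_result` with method "inverse_variance_fixed" or
#'   "dersimonian_laird_random".
#' @export
pool_inverse_variance <- function(effects, random = FALSE) {
  .check_effects(effects, 2)
  het <- cochran_q(effects)
  theta <- vapply(effects, function(e) e$log_or, numeric(1))
  se2 <- vapply(effects, function(e) e$se^2, numeric(1))
  tau2 <- if (random) het$tau_squared else 0
  w <- 1 / (se2 + tau2)
  log_or <- sum(w * theta) / sum(w)
  se <- 1 / sqrt(sum(w))
  method <- if (random) "dersimonian_laird_random" else "inverse_variance_fixed"
  .pooled_result(method, log_or, se, het, length(effects))
}

#' Heterogeneity-gated model choice
#'
#' Random effects are selected iff the heterogeneity p-value is strictly
#' below the configured alpha; otherwise the configured fixed-effects
#' method.
#'
#' @param het A `heterogeneity_result`.
#' @param cfg A `meta_config`.
#' @return Method tag: "dersimonian_laird_random",
#'   "mantel_haenszel_fixed" or "inverse_variance_fixed".
#' @export
select_model <- function(het, cfg = meta_config()) {
  stopifnot(inherits(het, "heterogeneity_result"),
            inherits(cfg, "meta_config"))
  if (het$p_value < cfg$heterogeneity_alpha)
    "dersimonian_laird_random"
  else if (cfg$fixed_method == "mh")
    "mantel_haenszel_fixed"
  else
    "inverse_variance_fixed"
}

.pool_by_method <- function(method, tables, effects, het) {
  switch(method,
    mantel_haenszel_fixed = pool_mantel_haenszel(tables, het = het),
    inverse_variance_fixed = pool_inverse_variance(effects, random = FALSE),
    dersimonian_laird_random = pool_inverse_variance(effects, random = TRUE),
    stop("unknown pooling method: ", method, call. = FALSE))
}

#' Full genotype-level meta-analysis of one SNP dataset
#'
#' For each of the four genetic-model contrasts: per-study odds ratios,
#' Cochran Q heterogeneity, and the pooled estimate by the
#' heterogeneity-gated method of [select_model()]. Controls of every study
#' are tested for Hardy-Weinberg equilibrium, and quality scores are
#' computed where study metadata are present.
#'
#' @param ds A `snp_dataset` with k >= 2 valid studies.
#' @param cfg A `meta_config`.
#' @return An object of class `snp_meta`: list with `snp_id`, `k`,
#'   `config`, `studies` (ids), `hwe` (per-study `hwe_result`), `quality`
#'   (per-study `quality_score` or NULL), and `models` — a named list (one
#'   entry per contrast) of `effects`, `heterogeneity`, `pooled`.
#' @export
meta_analyze <- function(ds, cfg = meta_config()) {
  stopifnot(inherits(ds, "snp_dataset"), inherits(cfg, "meta_config"))
  findings <- validate_dataset(ds)
  if (nrow(findings) > 0)
    stop(sprintf("invalid dataset: %s",
                 paste(sprintf("%s/%s: %s", findings$study_id,
                               findings$field, findings$message),
                       collapse = "; ")), call. = FALSE)
  k <- length(ds$studies)
  if (k < 2) stop("at least 2 studies required for pooling", call. = FALSE)
  ids <- vapply(ds$studies, function(s) s$study_id, character(1))
  hwe <- lapply(ds$studies, function(s) hwe_test(s$controls, cfg$hwe_alpha))
  names(hwe) <- ids
  quality <- lapply(ds$studies, function(s)
    if (is.null(s$metadata)) NULL else quality_score(s$metadata))
  names(quality) <- ids
  models <- lapply(genetic_models(), function(model) {
    tables <- lapply(ds$studies, function(s) build_contrast(s, model))
    effects <- tryCatch(lapply(tables, function(t) odds_ratio(t, cfg$cc)),
                        error = function(e)
                          stop(sprintf("[%s] %s", model, conditionMessage(e)),
                               call. = FALSE))
    names(effects) <- ids
    het <- cochran_q(effects)
    method <- select_model(het, cfg)
    pooled <- .pool_by_method(method, tables, effects, het)
    pooled$model <- model
    pooled$selected <- TRUE
    list(effects = effects, heterogeneity = het, pooled = pooled)
  })
  names(models) <- genetic_models()
  structure(list(snp_id = ds$snp_id, k = k, config = cfg, studies = ids,
                 hwe = hwe, quality = quality, models = models),
            class = "snp_meta")
}

#' @export
print.snp_meta <- function(x, ...) {
  cat(sprintf("Meta-analysis of %s (%d studies: %s)\n", x$snp_id, x$k,
              paste(x$studies, collapse = ", ")))
  for (m in names(x$models)) print(x$models[[m]]$pooled)
  invisible(x)
}

#' Leave-one-out sensitivity analysis
#'
#' Re-pools k times, the i-th run omitting study i, using the same
#' heterogeneity-gated model choice as [meta_analyze()]. Requires k >= 3
#' so that every reduced dataset still has two studies.
#'
#' @param ds A `snp_dataset` with k >= 3 studies.
#' @param model One of [genetic_models()].
#' @param cfg A `meta_config`.
#' @return List of k `pooled_result` objects, each with an `omitted` field
#'   naming the study left out.
#' @export
leave_one_out <- function(ds, model, cfg = meta_config()) {
  stopifnot(inherits(ds, "snp_dataset"))
  model <- match.arg(model, genetic_models())
  k <- length(ds$studies)
  if (k < 3)
    stop("at least 3 studies required for leave-one-out", call. = FALSE)
  lapply(seq_len(k), function(i) {
    sub <- snp_dataset(ds$snp_id, ds$studies[-i])
    tables <- lapply(sub$studies, function(s) build_contrast(s, model))
    effects <- lapply(tables, function(t) odds_ratio(t, cfg$cc))
    het <- cochran_q(effects)
    res <- .pool_by_method(select_model(het, cfg), tables, effects, het)
    res$model <- model
    res$omitted <- ds$studies[[i]]$study_id
    res
  })
}
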