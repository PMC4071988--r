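#' Egger's regression test for funnel-plot asymmetry
#'
#' Ordinary least squares of the standardized effects z_i = theta_i / se_i
#' on the precisions 1/se_i. Under a symmetric funnel the intercept is 0;
#' it is tested with a two-sided t-test on k - 2 degrees of freedom.
#'
#' @param effects List of `effect_estimate` objects; k >= 3 so df >= 1.
#' @return An object of class `egger_result` with `intercept`,
#'   `se_intercept`, `t_statistic`, `df`, `p_value`, `slope`.
#' @export
egger_test <- function(effects) {
  .check_effects(effects, 3)
  theta <- vapply(effects, function(e) e$log_or, numeric(1))
  se <- vapply(effects, function(e) e$se, numeric(1))
  z <- theta / se
  prec <- 1 / se
  fit <- stats::lm(z ~ prec)
  sm <- summary(fit)$coefficients
  k <- length(effects)
  structure(list(intercept = unname(sm["(Intercept)", "Estimate"]),
                 se_intercept = unname(sm["(Intercept)", "Std. Error"]),
                 t_statistic = unname(sm["(Intercept)", "t value"]),
                 df = k - 2L,
                 p_value = unname(sm["(Intercept)", "Pr(>|t|)"]),
                 # a constant-precision design (all SEs equal) leaves the
                 # slope inestimable; the intercept is then just mean(z)
                 slope = if ("prec" %in% rownames(sm))
                   unname(sm["prec", "Estimate"]) else NA_real_),
            class = "egger_result")
}

# All permutations of 1..n as an (n!) x n matrix; n is small (<= 8).
.permutations <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- .permutations(n - 1L)
  out <- matrix(0L, nrow = factorial(n), ncol = n)
  row <- 1L
  for (i in seq_len(n)) {
    rest <- seq_len(n)[-i]
    blk <- nrow(sub)
    out[row:(row + blk - 1L), 1L] <- i
    out[row:(row + blk - 1L), -1L] <- matrix(rest[sub], nrow = blk)
    row <- row + blk
  }
  out
}

# Kendall S (concordant minus discordant, ties contribute 0) and tau-b.
.kendall <- function(x, y) {
  n <- length(x)
  idx <- utils::combn(n, 2)
  dx <- sign(x[idx[1, ]] - x[idx[2, ]])
  dy <- sign(y[idx[1, ]] - y[idx[2, ]])
  s <- sum(dx * dy)
  n0 <- n * (n - 1) / 2
  tie_term <- function(v) {
    t <- table(v); sum(t * (t - 1) / 2)
  }
  t1 <- tie_term(x); t2 <- tie_term(y)
  denom <- sqrt((n0 - t1) * (n0 - t2))
  tau <- if (denom > 0) s / denom else 0
  list(s = s, tau = tau, n0 = n0, t1 = t1, t2 = t2)
}

#' Begg and Mazumdar's rank-correlation test for publication bias
#'
#' Kendall's rank correlation (tau-b for ties) between the
#' variance-standardized deviates t_i = (theta_i - theta_hat) /
#' sqrt(v_i - 1/sum(1/v_j)) and the sampling variances v_i = se_i^2,
#' where theta_hat is the inverse-variance fixed-effects pooled log OR.
#' The p-value is exact by permutation enumeration for k <= 8 and a
#' normal approximation with continuity correction (tie-corrected
#' variance of S) above.
#'
#' @param effects List of `effect_estimate` objects; k >= 3.
#' @return An object of class `begg_result` with `kendall_tau`, `s`,
#'   `p_value`, `exact`.
#' @export
begg_test <- function(effects) {
  .check_effects(effects, 3)
  theta <- vapply(effects, function(e) e$log_or, numeric(1))
  v <- vapply(effects, function(e) e$se^2, numeric(1))
  w <- 1 / v
  pooled <- sum(w * theta) / sum(w)
  vstar <- v - 1 / sum(w)
  # vstar is positive unless one study carries all the weight
  vstar <- pmax(vstar, .Machine$double.eps)
  tstar <- (theta - pooled) / sqrt(vstar)
  k <- length(effects)
  obs <- .kendall(tstar, v)
  if (k <= 8) {
    perms <- .permutations(k)
    taus <- apply(perms, 1, function(p) .kendall(tstar, v[p])$tau)
    p_value <- mean(abs(taus) >= abs(obs$tau) - 1e-12)
    exact <- TRUE
  } else {
    tie_v <- function(x) {
      t <- as.numeric(table(x))
      c(sum(t * (t - 1) * (2 * t + 5)),
        sum(t * (t - 1)), sum(t * (t - 1) * (t - 2)))
    }
    a <- tie_v(tstar); b <- tie_v(v)
    n <- k
    var_s <- (n * (n - 1) * (2 * n + 5) - a[1] - b[1]) / 18 +
      a[2] * b[2] / (2 * n * (n - 1)) +
      a[3] * b[3] / (9 * n * (n - 1) * (n - 2))
    z <- if (obs$s == 0) 0 else (abs(obs$s) - 1) / sqrt(var_s)
    p_value <- 2 * stats::pnorm(-abs(z))
    p_value <- min(1, p_value)
    exact <- FALSE
  }
  structure(list(kendall_tau = obs$tau, s = obs$s, p_value = p_value,
                 exact = exact), class = "begg_result")
}

#' Funnel-plot coordinates with pooled reference line and pseudo-CI wedge
#'
#' One point per study at (log OR, SE); by plotting convention the SE axis
#' is inverted at render time. The reference line sits at the
#' inverse-variance fixed-effects pooled log OR (the study's own effect
#' when k = 1), and the 95% pseudo-confidence wedge is pooled
#' +/- z_0.975 * se over a grid of SE values.
#'
#' @param effects List of `effect_estimate` objects; k >= 1. Names, when
#'   present, become study ids.
#' @param se_grid Numeric vector of SE values for the wedge; `NULL`
#'   (default) uses 50 points from 0 to 1.1 * max(se); a zero-length grid
#'   yields an empty `bounds` data frame.
#' @return List with `points` (data frame study_id, log_or, se),
#'   `reference` (pooled log OR), `bounds` (data frame se, lower, upper).
#' @export
funnel_data <- function(effects, se_grid = NULL) {
  .check_effects(effects, 1)
  theta <- vapply(effects, function(e) e$log_or, numeric(1))
  se <- vapply(effects, function(e) e$se, numeric(1))
  ids <- names(effects)
  if (is.null(ids)) ids <- paste0("study_", seq_along(effects))
  w <- 1 / se^2
  pooled <- sum(w * theta) / sum(w)
  if (is.null(se_grid)) se_grid <- seq(0, 1.1 * max(se), length.out = 50)
  bounds <- data.frame(se = se_grid,
                       lower = pooled - .z975 * se_grid,
                       upper = pooled + .z975 * se_grid)
  if (length(se_grid) == 0)
    bounds <- data.frame(se = numeric(), lower = numeric(),
                         upper = numeric())
  list(points = data.frame(study_id = ids, log_or = theta, se = se,
                           stringsAsFactors = FALSE),
       reference = pooled, bounds = bounds)
}
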