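# Shared builders for tiny in-code fixtures.

make_effect <- function(log_or, se) effect_estimate(log_or, se)

make_study <- function(id, case, ctrl, year = 2000) {
  study_record(id, year,
               genotype_counts(case[1], case[2], case[3]),
               genotype_counts(ctrl[1], ctrl[2], ctrl[3]))
}

# Two-study dataset with a mild protective variant; valid by construction.
toy_dataset <- function() {
  snp_dataset("toy", list(
    make_study("A", c(100, 80, 20), c(90, 90, 25)),
    make_study("B", c(210, 150, 35), c(180, 170, 50))))
}

# Independent closed-form OLS for the Egger regression (normal equations),
# kept free of lm() so it can serve as an oracle.
ols_line <- function(x, y) {
  n <- length(x)
  sxx <- sum((x - mean(x))^2)
  slope <- sum((x - mean(x)) * (y - mean(y))) / sxx
  intercept <- mean(y) - slope * mean(x)
  resid <- y - intercept - slope * x
  s2 <- sum(resid^2) / (n - 2)
  se_int <- sqrt(s2 * (1 / n + mean(x)^2 / sxx))
  list(intercept = intercept, slope = slope, se_intercept = se_int)
}
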