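#' Round half-up (school rounding), as printed tables do
#'
#' Base `round()` rounds half to even; published tables round half away
#' from zero, so comparisons against printed 2-decimal values use this.
#'
#' @param x Numeric vector.
#' @param digits Decimal places.
#' @return Rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 2) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

.effect_cells <- function(e) {
  c(or = e$or, ci_low = e$ci_low, ci_high = e$ci_high, p = e$p_value)
}

#' Flatten a meta-analysis into a report table
#'
#' One row per study plus a "Total" row, with genotype counts, the HWE
#' flag, and the OR / CI bounds / p for each of the four contrasts.
#' Values are unrounded; renderers round for display.
#'
#' @param meta A `snp_meta` from [meta_analyze()].
#' @return A data frame.
#' @export
report_table <- function(meta) {
  stopifnot(inherits(meta, "snp_meta"))
  rows <- lapply(seq_along(meta$studies), function(i) {
    id <- meta$studies[i]
    row <- data.frame(study_id = id,
                      hwe = meta$hwe[[id]]$in_equilibrium,
                      stringsAsFactors = FALSE)
    for (m in names(meta$models)) {
      cells <- .effect_cells(meta$models[[m]]$effects[[id]])
      names(cells) <- paste(m, names(cells), sep = "_")
      row <- cbind(row, as.data.frame(as.list(cells)))
    }
    row
  })
  total <- data.frame(study_id = "Total", hwe = NA, stringsAsFactors = FALSE)
  for (m in names(meta$models)) {
    cells <- .effect_cells(meta$models[[m]]$pooled$estimate)
    names(cells) <- paste(m, names(cells), sep = "_")
    total <- cbind(total, as.data.frame(as.list(cells)))
  }
  do.call(rbind, c(rows, list(total)))
}

.het_line <- function(meta) {
  vapply(names(meta$models), function(m) {
    h <- meta$models[[m]]$heterogeneity
    sprintf("%s: Q=%.3f df=%d p=%.3f I2=%.1f%%", m, h$q, h$df, h$p_value,
            100 * h$i_squared)
  }, character(1))
}

#' Render a meta-analysis report
#'
#' @param meta A `snp_meta` from [meta_analyze()].
#' @param format "markdown", "tsv" or "json". Markdown and TSV round
#'   ORs/CIs half-up to 2 decimals (publication style); JSON carries
#'   unrounded values.
#' @return A single character string in the requested format.
#' @export
render_report <- function(meta, format = c("markdown", "tsv", "json")) {
  format <- match.arg(format)
  tab <- report_table(meta)
  if (format == "json") {
    payload <- list(snp_id = meta$snp_id, k = meta$k,
                    method = meta$models[[1]]$pooled$method,
                    table = tab, heterogeneity = lapply(meta$models,
                      function(m) unclass(m$heterogeneity)))
    return(jsonlite::toJSON(payload, auto_unbox = TRUE, digits = NA,
                            dataframe = "rows"))
  }
  num <- vapply(tab, is.numeric, logical(1))
  shown <- tab
  shown[num] <- lapply(tab[num], function(x) round_half_up(x, 2))
  if (format == "tsv") {
    con <- textConnection("out", "w", local = TRUE)
    utils::write.table(shown, con, sep = "\t", row.names = FALSE,
                       quote = FALSE)
    close(con)
    return(paste(out, collapse = "\n"))
  }
  # markdown
  hdr <- paste0("| ", paste(names(shown), collapse = " | "), " |")
  sepline <- paste0("|", paste(rep("---", ncol(shown)), collapse = "|"), "|")
  body <- apply(shown, 1, function(r)
    paste0("| ", paste(r, collapse = " | "), " |"))
  paste(c(sprintf("### Meta-analysis of %s (k = %d)", meta$snp_id, meta$k),
          "", hdr, sepline, body, "",
          paste("Heterogeneity:", paste(.het_line(meta), collapse = "; "))),
        collapse = "\n")
}

#' Recompute every published odds-ratio cell and diff against the print
#'
#' Runs [meta_analyze()] on the packaged fixtures and compares every
#' per-study and pooled OR and CI bound with the 2-decimal values printed
#' in the source tables.
#'
#' @param snp_ids Fixtures to check; defaults to all three.
#' @param cfg A `meta_config`; the default (Mantel-Haenszel fixed effects,
#'   heterogeneity-gated) mirrors the published analysis.
#' @param tol Allowed absolute deviation from the printed value (default
#'   0.01, the print's own rounding resolution).
#' @return List with `comparison` (data frame: one row per compared
#'   number), `max_abs_dev`, and `all_within` (logical).
#' @export
reproduce_printed <- function(snp_ids = c("rs861539", "rs1799794",
                                          "rs1799796"),
                              cfg = meta_config(), tol = 0.01) {
  printed <- printed_results()
  rows <- list()
  for (snp in snp_ids) {
    meta <- meta_analyze(load_fixture(snp), cfg)
    sub <- printed[printed$snp_id == snp, ]
    for (i in seq_len(nrow(sub))) {
      r <- sub[i, ]
      est <- if (r$study_id == "Total")
        meta$models[[r$model]]$pooled$estimate
      else
        meta$models[[r$model]]$effects[[r$study_id]]
      got <- round_half_up(c(est$or, est$ci_low, est$ci_high), 2)
      want <- c(r$or, r$ci_low, r$ci_high)
      rows[[length(rows) + 1]] <- data.frame(
        snp_id = snp, study_id = r$study_id, model = r$model,
        quantity = c("or", "ci_low", "ci_high"),
        printed = want, computed = got, abs_dev = abs(got - want),
        stringsAsFactors = FALSE)
    }
  }
  comparison <- do.call(rbind, rows)
  max_dev <- max(comparison$abs_dev)
  list(comparison = comparison, max_abs_dev = max_dev,
       all_within = max_dev <= tol + 1e-12)
}
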