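# Monte-Carlo summaries: bias, precision (replicate SD), ratio of
# precision, and significance tests, per scenario and aggregated.

#' Summarise the replicates of one scenario
#'
#' Per estimator: mean, bias (mean minus true r2), and sample SD (n-1
#' denominator) over the defined replicates; the ratio of precision
#' `sd_hap / sd_geno` (values below 1 mean the haplotype route is more
#' precise); two-sided one-sample t-test p-values of the replicates
#' against the true r2; and the mean and SD of the per-replicate
#' difference `r2_geno - r2_hap`.
#'
#' @param reps A `"scenario_run"` from [run_scenario()], or a data frame
#'   with columns `r2_hap`, `r2_geno` and optionally `defined`.
#' @param true_r2 True crossbred r2; taken from the run object when `reps`
#'   is one.
#' @return A one-row data frame (scenario parameters included when
#'   available).
#' @export
summarize_scenario <- function(reps, true_r2 = NULL) {
  params <- NULL
  if (inherits(reps, "scenario_run")) {
    scn <- reps$scenario
    params <- data.frame(pM_A = scn$pM_A, pN_A = scn$pN_A,
                         pM_B = scn$pM_B, pN_B = scn$pN_B,
                         r2_A = scn$r2_A, r2_B = scn$r2_B,
                         n = scn$n, n_reps = scn$n_reps, seed = scn$seed)
    true_r2 <- reps$true$r2
    reps <- reps$replicates
  }
  if (is.null(true_r2)) {
    stop("true_r2 is required when summarising a plain replicate table",
         call. = FALSE)
  }
  if (is.null(reps$defined)) reps$defined <- TRUE
  ok <- reps$defined & !is.na(reps$r2_hap) & !is.na(reps$r2_geno)
  if (sum(ok) < 2) {
    stop("fewer than 2 defined replicates: cannot summarise", call. = FALSE)
  }
  hap <- reps$r2_hap[ok]
  geno <- reps$r2_geno[ok]
  sd_hap <- stats::sd(hap)
  sd_geno <- stats::sd(geno)
  ratio <- if (sd_geno > 0) sd_hap / sd_geno else NA_real_
  p_hap <- tryCatch(bias_test(hap, true_r2), error = function(e) NA_real_)
  p_geno <- tryCatch(bias_test(geno, true_r2), error = function(e) NA_real_)
  out <- data.frame(
    true_r2 = true_r2,
    mean_hap = mean(hap), bias_hap = mean(hap) - true_r2, sd_hap = sd_hap,
    mean_geno = mean(geno), bias_geno = mean(geno) - true_r2,
    sd_geno = sd_geno,
    ratio_precision = ratio,
    p_hap = p_hap, p_geno = p_geno,
    mean_abs_diff = mean(abs(geno - hap)),
    sd_diff = stats::sd(geno - hap),
    n_defined = sum(ok))
  if (!is.null(params)) out <- cbind(params, out)
  out
}

#' One-sample t-test of replicate estimates against the true value
#'
#' Tests whether the Monte-Carlo mean of an estimator differs from the
#' known true r2 (two-sided). This is the appropriate form for testing
#' estimator bias against a known constant.
#'
#' @param x Numeric vector of replicate estimates (>= 2 values).
#' @param true_r2 The known true value.
#' @return The two-sided p-value.
#' @export
bias_test <- function(x, true_r2) {
  x <- x[!is.na(x)]
  if (length(x) < 2) {
    stop("bias test needs at least 2 defined replicates", call. = FALSE)
  }
  if (stats::sd(x) == 0) {
    stop("degenerate bias test: zero replicate variance", call. = FALSE)
  }
  unname(stats::t.test(x, mu = true_r2)$p.value)
}

#' Welch test comparing the two estimators' replicate distributions
#'
#' Two-sample Welch t-test of haplotype-based versus genotype-based
#' replicate estimates. Offered for estimator-vs-estimator comparison;
#' for bias against the (constant) true r2 use [bias_test()].
#'
#' @param hap,geno Numeric vectors of replicate estimates.
#' @return The two-sided p-value.
#' @export
compare_estimators_test <- function(hap, geno) {
  unname(stats::t.test(hap, geno)$p.value)
}

#' Aggregate scenario summaries
#'
#' Unweighted means and maxima of |bias| and SD per estimator across
#' scenarios, overall and stratified by sample size, plus the average of
#' the per-scenario mean |r2_geno - r2_hap| and of its SD.
#'
#' @param summaries Data frame of scenario summaries ([run_grid()] output
#'   or rbind of [summarize_scenario()] rows) with a column `n` when
#'   stratification is wanted.
#' @return A data frame with one row per stratum (`"all"` first), columns
#'   `avg_abs_bias_hap/geno`, `max_abs_bias_hap/geno`, `avg_sd_hap/geno`,
#'   `max_sd_hap/geno`, `avg_mean_abs_diff`, `avg_sd_diff`, `n_scenarios`.
#' @export
aggregate_summaries <- function(summaries) {
  if (is.null(summaries) || nrow(summaries) == 0) {
    stop("no scenario summaries to aggregate", call. = FALSE)
  }
  one <- function(df, label) {
    data.frame(
      stratum = label,
      n_scenarios = nrow(df),
      avg_abs_bias_hap = mean(abs(df$bias_hap)),
      avg_abs_bias_geno = mean(abs(df$bias_geno)),
      max_abs_bias_hap = max(abs(df$bias_hap)),
      max_abs_bias_geno = max(abs(df$bias_geno)),
      avg_sd_hap = mean(df$sd_hap),
      avg_sd_geno = mean(df$sd_geno),
      max_sd_hap = max(df$sd_hap),
      max_sd_geno = max(df$sd_geno),
      avg_mean_abs_diff = mean(df$mean_abs_diff),
      avg_sd_diff = mean(df$sd_diff))
  }
  out <- one(summaries, "all")
  if (!is.null(summaries$n) && length(unique(summaries$n)) > 1) {
    for (nn in sort(unique(summaries$n))) {
      out <- rbind(out, one(summaries[summaries$n == nn, , drop = FALSE],
                            paste0("n=", nn)))
    }
  }
  rownames(out) <- NULL
  out
}

#' Ratio-of-precision table by stratum
#'
#' Min / mean / max of the per-scenario ratio `sd_hap / sd_geno` within
#' strata of either the within-line r2 level or the line frequency pair.
#'
#' @param summaries Scenario-summary data frame with columns
#'   `ratio_precision` and `r2_A` (for `by = "r2"`) or `pM_A`, `pM_B`
#'   (for `by = "freq_pair"`).
#' @param by Stratifying variable.
#' @return Data frame with columns `stratum`, `min`, `mean`, `max`,
#'   `n_scenarios`.
#' @export
precision_ratio_table <- function(summaries, by = c("r2", "freq_pair")) {
  by <- match.arg(by)
  if (by == "r2") {
    if (is.null(summaries$r2_A)) stop("missing stratum column: r2_A",
                                      call. = FALSE)
    key <- format(summaries$r2_A)
  } else {
    if (is.null(summaries$pM_A) || is.null(summaries$pM_B)) {
      stop("missing stratum columns: pM_A / pM_B", call. = FALSE)
    }
    key <- paste0(format(summaries$pM_A), "/", format(summaries$pM_B))
  }
  strata <- sort(unique(key))
  out <- do.call(rbind, lapply(strata, function(s) {
    r <- summaries$ratio_precision[key == s]
    data.frame(stratum = s, min = min(r), mean = mean(r), max = max(r),
               n_scenarios = length(r))
  }))
  rownames(out) <- NULL
  out
}

#' Plot the ratio of precision against scenario parameters
#'
#' One panel: per-scenario ratio `sd_hap / sd_geno` against the line-A
#' minor allele frequency, one line per within-line r2 level. A ratio
#' below 1 means the haplotype-based estimator is the more precise one.
#'
#' @param summaries Scenario-summary data frame (diagonal-frequency
#'   scenarios are most readable).
#' @param ... Passed to [graphics::plot()].
#' @return Invisibly, the summaries.
#' @export
plot_precision_ratio <- function(summaries, ...) {
  r2s <- sort(unique(summaries$r2_A))
  cols <- grDevices::hcl.colors(max(length(r2s), 2), "Dark 2")
  graphics::plot(NA, xlim = range(summaries$pM_A),
                 ylim = c(min(summaries$ratio_precision, 0.65), 1),
                 xlab = "minor allele frequency (line A)",
                 ylab = "ratio of precision (SD hap / SD geno)", ...)
  graphics::abline(h = 1, lty = 3)
  for (k in seq_along(r2s)) {
    sub <- summaries[summaries$r2_A == r2s[k] &
                       summaries$pM_A == summaries$pM_B, , drop = FALSE]
    sub <- sub[order(sub$pM_A), ]
    graphics::lines(sub$pM_A, sub$ratio_precision, type = "b", col = cols[k],
                    pch = 19)
  }
  graphics::legend("bottomleft", legend = paste0("r2 = ", r2s),
                   col = cols[seq_along(r2s)], lty = 1, pch = 19, bty = "n")
  invisible(summaries)
}
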