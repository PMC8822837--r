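# Monte-Carlo machinery: scenario grids, multinomial sampling of crossbred
# samples, and replicate execution.
#
# A crossbred individual is one line-A haplotype paired with one line-B
# haplotype, independently under random mating, so a sample of n
# individuals is a single multinomial draw of size n over the 16 ordered
# (hap A, hap B) categories with cell probabilities hA_i * hB_j. This is
# distributionally identical to sampling n haplotypes per line and pairing
# them uniformly at random (the explicit route is kept as a slow reference
# sampler), but orders of magnitude faster.

#' Define one simulation scenario
#'
#' A scenario fixes the parental-line parameters (allele frequencies at
#' both loci, within-line r2, phase sign of D), the crossbred sample size,
#' the replicate count, and a seed. Feasibility of each (frequency, r2)
#' combination is checked at construction time.
#'
#' @param pM_A,pN_A,pM_B,pN_B Allele-1 frequencies at loci M and N in lines
#'   A and B, strictly in (0, 1).
#' @param r2_A,r2_B Within-line squared correlation, in \[0, 1\].
#' @param phase_A,phase_B Sign of within-line D (+1 coupling, -1
#'   repulsion); default coupling.
#' @param n Number of crossbred individuals per replicate (>= 2).
#' @param n_reps Number of Monte-Carlo replicates (>= 1).
#' @param seed Integer seed for this scenario.
#' @return A list of class `"cross_scenario"` with the parameters plus the
#'   derived line haplotype frequencies `hA`, `hB`.
#' @export
cross_scenario <- function(pM_A, pN_A, pM_B, pN_B, r2_A, r2_B,
                           phase_A = 1, phase_B = 1,
                           n = 900, n_reps = 1000, seed = 1L) {
  if (n < 2) stop("sample size n must be >= 2", call. = FALSE)
  if (n_reps < 1) stop("n_reps must be >= 1", call. = FALSE)
  hA <- hap_freqs_from_params(pM_A, pN_A, r2_A, phase_A)
  hB <- hap_freqs_from_params(pM_B, pN_B, r2_B, phase_B)
  structure(list(pM_A = pM_A, pN_A = pN_A, pM_B = pM_B, pN_B = pN_B,
                 r2_A = r2_A, r2_B = r2_B,
                 phase_A = sign(phase_A), phase_B = sign(phase_B),
                 n = as.integer(n), n_reps = as.integer(n_reps),
                 seed = as.integer(seed), hA = hA, hB = hB),
            class = "cross_scenario")
}

#' @export
print.cross_scenario <- function(x, ...) {
  cat(sprintf(
    "Cross scenario: line A (pM=%.3g, pN=%.3g, r2=%.3g), line B (pM=%.3g, pN=%.3g, r2=%.3g)\n",
    x$pM_A, x$pN_A, x$r2_A, x$pM_B, x$pN_B, x$r2_B))
  cat(sprintf("  n = %d individuals, %d replicates, seed %d\n",
              x$n, x$n_reps, x$seed))
  invisible(x)
}

# Counter-based per-scenario seed so scenarios are independent and
# individually re-runnable; kept below 2^31 - 1.
derive_seed <- function(master_seed, index) {
  as.integer((as.numeric(master_seed) %% 65521 * 32749 + index * 7919) %%
               2147483629)
}

#' Build a grid of simulation scenarios
#'
#' Crosses unordered pairs of allele-frequency levels (equal at both loci
#' within a line) with r2 levels (equal in both lines) and sample sizes.
#' The defaults reproduce the standard study grid: frequency levels 0.05 to
#' 0.45 by 0.10 (15 unordered pairs), r2 in \{0.2, 0.4, 0.6, 0.8\}, n in
#' \{900, 1800, 2700\} -- 180 scenarios. Each scenario receives a
#' deterministic seed derived from `seed` and its grid index.
#'
#' @param freq_levels Allele-frequency levels; unordered pairs (with
#'   repetition) become the line-A / line-B frequencies.
#' @param r2_levels Within-line r2 levels.
#' @param sample_sizes Crossbred sample sizes.
#' @param n_reps Replicates per scenario.
#' @param seed Master seed.
#' @param phase Sign of within-line D for both lines.
#' @return A list of [cross_scenario()] objects.
#' @examples
#' length(build_scenario_grid())  # 180
#' @export
build_scenario_grid <- function(freq_levels = c(0.05, 0.15, 0.25, 0.35, 0.45),
                                r2_levels = c(0.2, 0.4, 0.6, 0.8),
                                sample_sizes = c(900, 1800, 2700),
                                n_reps = 1000, seed = 1L, phase = 1) {
  freq_levels <- sort(freq_levels)
  pairs <- list()
  for (a in seq_along(freq_levels)) {
    for (b in a:length(freq_levels)) {
      pairs[[length(pairs) + 1L]] <- c(freq_levels[a], freq_levels[b])
    }
  }
  scenarios <- list()
  idx <- 0L
  for (n in sample_sizes) {
    for (r2 in r2_levels) {
      for (pr in pairs) {
        idx <- idx + 1L
        scenarios[[idx]] <- cross_scenario(
          pM_A = pr[1], pN_A = pr[1], pM_B = pr[2], pN_B = pr[2],
          r2_A = r2, r2_B = r2, phase_A = phase, phase_B = phase,
          n = n, n_reps = n_reps, seed = derive_seed(seed, idx))
      }
    }
  }
  scenarios
}

#' Sample one crossbred dataset
#'
#' Draws the 4x4 haplotype-pair counts for `scn$n` crossbred individuals
#' from the 16-category multinomial with cell probabilities `hA_i * hB_j`.
#' Uses the current RNG state (seed management is the caller's job; see
#' [run_scenario()]).
#'
#' @param scn A [cross_scenario()].
#' @param method `"multinomial"` (default, direct) or `"pairing"` (slow
#'   reference: sample n haplotypes per line, pair uniformly at random).
#' @return A [pair_counts()] table.
#' @export
sample_crossbred <- function(scn, method = c("multinomial", "pairing")) {
  method <- match.arg(method)
  if (method == "multinomial") {
    p16 <- as.vector(outer(as.numeric(scn$hA), as.numeric(scn$hB)))
    counts <- matrix(stats::rmultinom(1, scn$n, p16), 4, 4)
  } else {
    hapsA <- sample.int(4L, scn$n, replace = TRUE, prob = as.numeric(scn$hA))
    hapsB <- sample.int(4L, scn$n, replace = TRUE, prob = as.numeric(scn$hB))
    hapsB <- hapsB[sample.int(scn$n)]  # random pairing
    counts <- matrix(0, 4, 4)
    for (k in seq_len(scn$n)) {
      counts[hapsA[k], hapsB[k]] <- counts[hapsA[k], hapsB[k]] + 1
    }
  }
  pair_counts(counts)
}

# Vectorised estimator evaluation over a 16 x n_reps count matrix
# (cells in column-major order of the 4x4 table: line-A hap varies
# fastest). Returns both estimators per replicate; must agree with
# estimate_ld_haplotype() / estimate_ld_genotype() applied per replicate.
.replicate_estimates <- function(counts16, n) {
  i_idx <- rep(1:4, times = 4)  # line-A hap of each of the 16 cells
  j_idx <- rep(1:4, each = 4)   # line-B hap
  IA <- matrix(0, 4, 16); IA[cbind(i_idx, 1:16)] <- 1
  IB <- matrix(0, 4, 16); IB[cbind(j_idx, 1:16)] <- 1
  cA <- IA %*% counts16  # 4 x R line-A haplotype counts
  cB <- IB %*% counts16

  pM_A <- (cA[3, ] + cA[4, ]) / n
  pN_A <- (cA[2, ] + cA[4, ]) / n
  pM_B <- (cB[3, ] + cB[4, ]) / n
  pN_B <- (cB[2, ] + cB[4, ]) / n
  D_A <- cA[4, ] / n - pM_A * pN_A
  D_B <- cB[4, ] / n - pM_B * pN_B
  varM <- pM_A * (1 - pM_A) + pM_B * (1 - pM_B)
  varN <- pN_A * (1 - pN_A) + pN_B * (1 - pN_B)
  den_hap <- varN * varM
  r2_hap <- ifelse(den_hap > 0, (D_A + D_B)^2 / den_hap, NA_real_)

  dM <- .ALLELE_M[i_idx] + .ALLELE_M[j_idx]
  dN <- .ALLELE_N[i_idx] + .ALLELE_N[j_idx]
  EM <- drop(crossprod(dM, counts16)) / n
  EN <- drop(crossprod(dN, counts16)) / n
  EM2 <- drop(crossprod(dM^2, counts16)) / n
  EN2 <- drop(crossprod(dN^2, counts16)) / n
  EMN <- drop(crossprod(dM * dN, counts16)) / n
  varMg <- EM2 - EM^2
  varNg <- EN2 - EN^2
  covg <- EMN - EM * EN
  r2_geno <- ifelse(varMg > 0 & varNg > 0, covg^2 / (varMg * varNg),
                    NA_real_)

  data.frame(r2_hap = r2_hap, r2_geno = r2_geno,
             defined = !is.na(r2_hap) & !is.na(r2_geno))
}

#' Run all replicates of one scenario
#'
#' Seeds the RNG with the scenario seed, computes the true crossbred r2
#' once as the benchmark, then draws `n_reps` multinomial samples and
#' applies both estimators to each. Replicates where either estimator is
#' undefined (a monomorphic sample margin) are flagged and excluded from
#' downstream summaries; at the default scales (MAF >= 0.05, n >= 900)
#' they essentially never occur.
#'
#' @param scn A [cross_scenario()].
#' @param engine `"vectorised"` (default) evaluates both estimators on the
#'   stacked count matrix; `"loop"` calls [estimate_ld_haplotype()] and
#'   [estimate_ld_genotype()] replicate by replicate (identical results,
#'   kept for cross-checking).
#' @param sampler Passed to [sample_crossbred()] when `engine = "loop"`.
#' @return A list of class `"scenario_run"`: `scenario`, `true` (an
#'   [ld_value()]), `replicates` (data frame with columns `replicate`,
#'   `r2_hap`, `r2_geno`, `defined`), and `n_undefined`.
#' @export
run_scenario <- function(scn, engine = c("vectorised", "loop"),
                         sampler = "multinomial") {
  engine <- match.arg(engine)
  set.seed(scn$seed)
  true <- crossbred_true_ld(scn$hA, scn$hB)
  if (engine == "vectorised") {
    p16 <- as.vector(outer(as.numeric(scn$hA), as.numeric(scn$hB)))
    counts16 <- stats::rmultinom(scn$n_reps, scn$n, p16)
    est <- .replicate_estimates(counts16, scn$n)
  } else {
    est <- data.frame(r2_hap = numeric(scn$n_reps),
                      r2_geno = numeric(scn$n_reps),
                      defined = logical(scn$n_reps))
    for (r in seq_len(scn$n_reps)) {
      pc <- sample_crossbred(scn, method = sampler)
      lh <- estimate_ld_haplotype(pc)
      lg <- estimate_ld_genotype(pair_counts_to_dosage(pc))
      est$r2_hap[r] <- lh$r2
      est$r2_geno[r] <- lg$r2
      est$defined[r] <- lh$defined && lg$defined
    }
  }
  est$replicate <- seq_len(nrow(est))
  n_undef <- sum(!est$defined)
  if (n_undef > 0) {
    message(sprintf("scenario seed %d: %d of %d replicates undefined, excluded",
                    scn$seed, n_undef, scn$n_reps))
  }
  structure(list(scenario = scn, true = true,
                 replicates = est[, c("replicate", "r2_hap", "r2_geno",
                                      "defined")],
                 n_undefined = n_undef),
            class = "scenario_run")
}

#' Run a list of scenarios and summarise each
#'
#' Convenience wrapper: [run_scenario()] then [summarize_scenario()] for
#' every element, bound into one data frame (one row per scenario with its
#' parameters and summary statistics).
#'
#' @param scenarios A list of [cross_scenario()] objects, e.g. from
#'   [build_scenario_grid()].
#' @param keep_replicates If `TRUE`, the per-replicate data frames are
#'   attached as attribute `"replicates"` (a list).
#' @return A data frame of scenario summaries.
#' @export
run_grid <- function(scenarios, keep_replicates = FALSE) {
  reps_list <- if (keep_replicates) vector("list", length(scenarios))
  rows <- vector("list", length(scenarios))
  for (k in seq_along(scenarios)) {
    run <- run_scenario(scenarios[[k]])
    rows[[k]] <- summarize_scenario(run)
    if (keep_replicates) reps_list[[k]] <- run$replicates
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  if (keep_replicates) attr(out, "replicates") <- reps_list
  out
}
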