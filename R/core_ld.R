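# Closed-form population-level LD theory for an F1 cross of two lines.
#
# Two routes to the true crossbred r2 are implemented independently:
#   * the haplotype route: square of the average of the per-line gametic
#     covariances over the product of the averaged per-locus variances;
#   * the genotype route: dosage moments of the 4x4 crossbred genotype
#     table, then cov^2 / (var * var).
# The two are algebraically identical; the test suite checks agreement to
# 1e-12 on random inputs.

#' Expected allele frequency in the crossbreds
#'
#' Under random mating between two lines, the crossbred frequency of allele
#' 1 at a locus is the average of the two line frequencies.
#'
#' @param pA,pB Allele-1 frequency at the locus in lines A and B, in
#'   \[0, 1\].
#' @return `(pA + pB) / 2`.
#' @export
crossbred_allele_freq <- function(pA, pB) {
  .check_prob(pA, "pA")
  .check_prob(pB, "pB")
  (pA + pB) / 2
}

#' Crossbred inbreeding coefficient at one locus
#'
#' In an F1 cross the genotype-11 frequency is `pA * pB`, while
#' Hardy-Weinberg with crossbred frequency `p = (pA + pB)/2` predicts
#' `p^2`. The inbreeding coefficient f measures the departure, defined by
#' `pA * pB = p^2 + p (1 - p) f`. Solving gives
#' `f = -(pA - pB)^2 / ((pA + pB) (2 - pA - pB))`, which is never positive:
#' crossbreds show a heterozygote excess, and f = 0 only when the two lines
#' have equal frequency.
#'
#' @param pA,pB Allele-1 frequency at the locus in lines A and B.
#' @return The inbreeding coefficient, a number <= 0.
#' @seealso [inbreeding_coefficient_printed()] for a legacy variant with a
#'   different denominator.
#' @examples
#' inbreeding_coefficient(0.05, 0.09)
#' @export
inbreeding_coefficient <- function(pA, pB) {
  .check_prob(pA, "pA")
  .check_prob(pB, "pB")
  p <- (pA + pB) / 2
  if (p <= 0 || p >= 1) {
    stop("inbreeding coefficient undefined: crossbred locus is monomorphic",
         call. = FALSE)
  }
  (pA * pB - p^2) / (p * (1 - p))
}

#' Crossbred inbreeding coefficient, legacy denominator variant
#'
#' Evaluates `-(pA - pB)^2 / ((pA + pB) * (2 - pA + pB))`. This denominator
#' (`2 - pA + pB` rather than `2 - pA - pB`) is inconsistent with the
#' defining Hardy-Weinberg-departure relation but circulates in the
#' literature; it is kept so that published worked examples can be
#' reproduced exactly. [inbreeding_coefficient()] is the
#' derivation-consistent form and should be preferred.
#'
#' @inheritParams inbreeding_coefficient
#' @return The value of the printed expression.
#' @export
inbreeding_coefficient_printed <- function(pA, pB) {
  .check_prob(pA, "pA")
  .check_prob(pB, "pB")
  den <- (pA + pB) * (2 - pA + pB)
  if (den == 0) {
    stop("inbreeding coefficient undefined: zero denominator", call. = FALSE)
  }
  -(pA - pB)^2 / den
}

#' Feasible range of the gametic covariance D
#'
#' For allele frequencies `pM`, `pN` at the two loci, D is constrained to
#' `[-min(pM pN, (1-pM)(1-pN)), min(pM (1-pN), (1-pM) pN)]`.
#'
#' @param pM,pN Allele-1 frequencies, both in (0, 1).
#' @return Named numeric vector `c(Dmin =, Dmax =)`.
#' @export
d_bounds <- function(pM, pN) {
  .check_prob(pM, "pM")
  .check_prob(pN, "pN")
  if (pM <= 0 || pM >= 1 || pN <= 0 || pN >= 1) {
    stop("D bounds undefined: monomorphic locus", call. = FALSE)
  }
  c(Dmin = -min(pM * pN, (1 - pM) * (1 - pN)),
    Dmax = min(pM * (1 - pN), (1 - pM) * pN))
}

#' Build line haplotype frequencies from allele frequencies and r2
#'
#' Converts a (pM, pN, r2, phase) parameterisation into the four haplotype
#' frequencies: `D = phase * sqrt(r2 * pM (1-pM) * pN (1-pN))` and
#' `f11 = pM pN + D` etc. Errors if the requested r2 is infeasible for the
#' given frequencies, reporting the admissible maximum.
#'
#' @param pM,pN Allele-1 frequencies at loci M and N, in (0, 1).
#' @param r2 Within-line squared correlation, in \[0, 1\].
#' @param phase Sign of D: `+1` (coupling, default) or `-1` (repulsion).
#' @return A [line_hap_freqs()] object whose [line_ld()] recovers `r2`.
#' @examples
#' h <- hap_freqs_from_params(0.45, 0.45, r2 = 0.2)
#' line_ld(h)$r2
#' @export
hap_freqs_from_params <- function(pM, pN, r2, phase = 1) {
  .check_prob(pM, "pM")
  .check_prob(pN, "pN")
  if (pM <= 0 || pM >= 1 || pN <= 0 || pN >= 1) {
    stop("allele frequencies must lie strictly in (0, 1)", call. = FALSE)
  }
  if (!is.numeric(r2) || length(r2) != 1L || is.na(r2) || r2 < 0 || r2 > 1) {
    stop("r2 must be a number in [0, 1]", call. = FALSE)
  }
  phase <- sign(phase)
  if (!phase %in% c(-1, 1)) {
    stop("phase must be +1 (coupling) or -1 (repulsion)", call. = FALSE)
  }
  varM <- pM * (1 - pM)
  varN <- pN * (1 - pN)
  D <- phase * sqrt(r2 * varM * varN)
  b <- d_bounds(pM, pN)
  if (D < b["Dmin"] - .SUM_TOL || D > b["Dmax"] + .SUM_TOL) {
    r2max <- if (phase > 0) b["Dmax"]^2 / (varM * varN) else
      b["Dmin"]^2 / (varM * varN)
    stop(sprintf(
      "r2 = %.4g infeasible for pM = %.4g, pN = %.4g, phase %+d (max feasible r2 = %.6g)",
      r2, pM, pN, phase, r2max), call. = FALSE)
  }
  line_hap_freqs((1 - pM) * (1 - pN) + D,
                 (1 - pM) * pN - D,
                 pM * (1 - pN) - D,
                 pM * pN + D)
}

#' Within-line LD from haplotype frequencies
#'
#' The gametic covariance is `D = f11 - pM pN` (observed coupling frequency
#' minus the linkage-equilibrium expectation); allele counts on a haplotype
#' are Bernoulli so the per-locus variances are `p (1 - p)`, giving
#' `r2 = D^2 / (pM (1-pM) pN (1-pN))`. D' is Lewontin's normalisation,
#' `D / Dmax` for D >= 0 and `D / |Dmin|` otherwise.
#'
#' @param h A [line_hap_freqs()] object.
#' @return An [ld_value()]; `defined = FALSE` if a locus is monomorphic.
#' @export
line_ld <- function(h) {
  m <- hap_marginals(h)
  D <- unname(h[4]) - m["pM"] * m["pN"]
  .ld_from_D(unname(D), unname(m["pM"]), unname(m["pN"]))
}

# r2/D/D' from a covariance and the two allele frequencies (shared by the
# line-level and crossbred-level routes).
.ld_from_D <- function(D, pM, pN) {
  den <- pM * (1 - pM) * pN * (1 - pN)
  if (den <= 0) {
    return(ld_value(NA_real_, NA_real_, NA_real_, defined = FALSE))
  }
  r2 <- D^2 / den
  if (D >= 0) {
    dmax <- min(pM * (1 - pN), (1 - pM) * pN)
    dp <- if (dmax > 0) D / dmax else 0
  } else {
    dmin <- min(pM * pN, (1 - pM) * (1 - pN))
    dp <- D / dmin  # dmin > 0 whenever den > 0
  }
  ld_value(r2 = r2, D = D, Dprime = dp)
}

#' True crossbred LD from the parental haplotype frequencies
#'
#' The haplotype route: an F1 crossbred carries one haplotype from each
#' line, so its two-locus covariance is the average of the per-line gametic
#' covariances and its per-locus variance is the average of the per-line
#' Bernoulli variances. Hence
#' \deqn{r^2 = \frac{(D_A + D_B)^2}{(v_{NA} + v_{NB})(v_{MA} + v_{MB})},}
#' where \eqn{v} are the per-line allele-count variances `p (1 - p)` (the
#' factors of 2 from averaging cancel). The crossbred D is
#' `(D_A + D_B) / 2`, and D' uses the crossbred (averaged) allele
#' frequencies.
#'
#' @param hA,hB [line_hap_freqs()] for lines A and B.
#' @return An [ld_value()]; `defined = FALSE` when the crossbred population
#'   is monomorphic at either locus.
#' @examples
#' hA <- hap_freqs_from_params(0.05, 0.05, 0.2)
#' hB <- hap_freqs_from_params(0.45, 0.45, 0.2)
#' crossbred_true_ld(hA, hB)
#' @export
crossbred_true_ld <- function(hA, hB) {
  mA <- hap_marginals(hA)
  mB <- hap_marginals(hB)
  DA <- unname(hA[4]) - mA["pM"] * mA["pN"]
  DB <- unname(hB[4]) - mB["pM"] * mB["pN"]
  varM <- mA["pM"] * (1 - mA["pM"]) + mB["pM"] * (1 - mB["pM"])
  varN <- mA["pN"] * (1 - mA["pN"]) + mB["pN"] * (1 - mB["pN"])
  den <- unname(varN * varM)
  pM <- unname((mA["pM"] + mB["pM"]) / 2)
  pN <- unname((mA["pN"] + mB["pN"]) / 2)
  if (den <= 0 || pM <= 0 || pM >= 1 || pN <= 0 || pN >= 1) {
    return(ld_value(NA_real_, NA_real_, NA_real_, defined = FALSE))
  }
  Dcross <- unname(DA + DB) / 2
  r2 <- unname(DA + DB)^2 / den
  # D' on the crossbred allele-frequency scale
  dp <- .ld_from_D(Dcross, pM, pN)$Dprime
  ld_value(r2 = r2, D = Dcross, Dprime = dp)
}

#' Expected crossbred genotype frequencies
#'
#' Under random mating between the lines, the line-A and line-B haplotypes
#' of a crossbred are independent, so the 4x4 table of ordered genotype
#' (haplotype-pair) frequencies is the outer product of the two line
#' frequency vectors.
#'
#' @inheritParams crossbred_true_ld
#' @return A 4x4 matrix; rows = line-A haplotype, columns = line-B
#'   haplotype; cells sum to 1 and margins reproduce `hA`, `hB`.
#' @export
crossbred_genotype_freqs <- function(hA, hB) {
  tab <- outer(as.numeric(hA), as.numeric(hB))
  dimnames(tab) <- list(line_A = .HAP_LABELS, line_B = .HAP_LABELS)
  tab
}

#' Expected dosage moments in the crossbreds
#'
#' First and second moments of the genotype dosages (0/1/2 copies of allele
#' 1) at the two loci, and their cross moment, written in the line
#' haplotype frequencies (r, s, t, u) = (f00, f01, f10, f11) and primed for
#' line B:
#' \itemize{
#'   \item `E(Mg)  = (t+u) + (t'+u')`
#'   \item `E(Mg2) = (t+u) + (t'+u') + 2 (t'+u') (t+u)`
#'   \item `E(Ng)  = (s+u) + (s'+u')`
#'   \item `E(Ng2) = (s+u) + (s'+u') + 2 (s'+u') (s+u)`
#'   \item `E(MgNg) = u'(1 + t + u) + u (1 + t' + u') + s'(t+u) + s (t'+u')`
#' }
#'
#' @inheritParams crossbred_true_ld
#' @return A list of class `"dosage_moments"` with elements `E_Mg`, `E_Ng`,
#'   `E_Mg2`, `E_Ng2`, `E_MgNg`.
#' @export
dosage_moments <- function(hA, hB) {
  s <- unname(hA[2]); t_ <- unname(hA[3]); u <- unname(hA[4])
  sp <- unname(hB[2]); tp <- unname(hB[3]); up <- unname(hB[4])
  structure(list(
    E_Mg   = (t_ + u) + (tp + up),
    E_Ng   = (s + u) + (sp + up),
    E_Mg2  = (t_ + u) + (tp + up) + 2 * (tp + up) * (t_ + u),
    E_Ng2  = (s + u) + (sp + up) + 2 * (sp + up) * (s + u),
    E_MgNg = up * (1 + t_ + u) + u * (1 + tp + up) +
      sp * (t_ + u) + s * (tp + up)
  ), class = "dosage_moments")
}

#' Crossbred r2 from dosage moments
#'
#' The genotype route: `cov(Mg, Ng) = E(MgNg) - E(Mg) E(Ng)`,
#' `var(Mg) = E(Mg2) - E(Mg)^2`, and `r2 = cov^2 / (var_M var_N)`. For any
#' valid pair of parental haplotype-frequency sets this equals the
#' haplotype-route value from [crossbred_true_ld()] exactly. The gametic-
#' scale D is `cov / 2` and D' uses the crossbred allele frequencies
#' `E(Mg)/2`, `E(Ng)/2`.
#'
#' @param m A `"dosage_moments"` object from [dosage_moments()].
#' @return An [ld_value()]; `defined = FALSE` when a dosage variance is
#'   zero.
#' @export
crossbred_r2_from_moments <- function(m) {
  covg <- m$E_MgNg - m$E_Mg * m$E_Ng
  varM <- m$E_Mg2 - m$E_Mg^2
  varN <- m$E_Ng2 - m$E_Ng^2
  if (varM <= 0 || varN <= 0) {
    return(ld_value(NA_real_, NA_real_, NA_real_, defined = FALSE))
  }
  r2 <- covg^2 / (varM * varN)
  D <- covg / 2
  dp <- .ld_from_D(D, m$E_Mg / 2, m$E_Ng / 2)$Dprime
  ld_value(r2 = r2, D = D, Dprime = dp)
}

.check_prob <- function(p, name) {
  if (!is.numeric(p) || length(p) != 1L || is.na(p) || p < 0 || p > 1) {
    stop(sprintf("%s must be a single probability in [0, 1]", name),
         call. = FALSE)
  }
  invisible(TRUE)
}
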