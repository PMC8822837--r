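# Sample-based LD estimators for a crossbred dataset.
#
# Both estimators consume the same sufficient statistic, the 4x4
# pair_counts table. The haplotype route plugs per-line sample haplotype
# frequencies into the crossbred formula; the genotype route discards
# phase (pair_counts -> dosage_sample) and squares the Pearson correlation
# of the 0/1/2 dosages. The information the genotype route loses is
# exactly the coupling/repulsion split of double heterozygotes.

# Dosage carried by the (line-A hap i, line-B hap j) cell, row-major 4x4.
.CELL_DOSAGE_M <- outer(.ALLELE_M, .ALLELE_M, `+`)
.CELL_DOSAGE_N <- outer(.ALLELE_N, .ALLELE_N, `+`)

#' Haplotype-based LD estimator
#'
#' Plug-in estimator of the crossbred r2 from phased data: the row margin
#' of `pc` gives the line-A sample haplotype frequencies, the column margin
#' the line-B frequencies, and these are substituted into the
#' population formula ([crossbred_true_ld()]). The per-line form keeps the
#' estimator aimed at the crossbred-population r2 even when line allele
#' frequencies differ.
#'
#' With `pooled = TRUE` the 2n haplotypes of both lines are pooled into a
#' single frequency set and [line_ld()] is applied. This estimates a
#' different target: pooling adds a between-line covariance term
#' `(pM_A - pM_B)(pN_A - pN_B) / 4` to D and is biased for the crossbred
#' r2 when the lines differ in frequency at both loci.
#'
#' @param pc A [pair_counts()] table.
#' @param pooled Pool the two lines' haplotypes before computing LD?
#'   Default `FALSE` (per-line plug-in).
#' @return An [ld_value()]; `defined = FALSE` if a required margin is
#'   monomorphic in the sample.
#' @examples
#' pc <- pair_counts(diag(c(4, 1, 1, 4)))
#' estimate_ld_haplotype(pc)$r2  # 0.36
#' @export
estimate_ld_haplotype <- function(pc, pooled = FALSE) {
  n <- attr(pc, "n")
  if (is.null(n) || n == 0) {
    stop("empty sample: no individuals in pair counts", call. = FALSE)
  }
  if (n < 2) {
    stop("at least 2 individuals are required", call. = FALSE)
  }
  fA <- rowSums(pc) / n
  fB <- colSums(pc) / n
  if (pooled) {
    return(line_ld(line_hap_freqs((fA + fB) / 2)))
  }
  crossbred_true_ld(line_hap_freqs(fA), line_hap_freqs(fB))
}

#' Genotype-based (dosage-correlation) LD estimator
#'
#' Rogers-Huff-style estimator from unphased data: the squared sample
#' Pearson correlation between the allele-1 dosages (0/1/2) at the two
#' loci. Moments are population-style (divide by n); r2 is invariant to
#' the n vs n-1 choice. D is reported on the gametic scale as half the
#' dosage covariance, and D' uses the sample allele frequencies
#' (mean dosage / 2).
#'
#' @param ds A [dosage_sample()] table.
#' @return An [ld_value()]; `defined = FALSE` if either dosage variance is
#'   zero.
#' @export
estimate_ld_genotype <- function(ds) {
  n <- attr(ds, "n")
  if (is.null(n) || n == 0) {
    stop("empty sample: no individuals in dosage table", call. = FALSE)
  }
  if (n < 2) {
    stop("at least 2 individuals are required", call. = FALSE)
  }
  d <- 0:2
  EM <- sum(rowSums(ds) * d) / n
  EN <- sum(colSums(ds) * d) / n
  EM2 <- sum(rowSums(ds) * d^2) / n
  EN2 <- sum(colSums(ds) * d^2) / n
  EMN <- sum(ds * outer(d, d)) / n
  covg <- EMN - EM * EN
  varM <- EM2 - EM^2
  varN <- EN2 - EN^2
  if (varM <= 0 || varN <= 0) {
    return(ld_value(NA_real_, NA_real_, NA_real_, defined = FALSE))
  }
  r2 <- covg^2 / (varM * varN)
  D <- covg / 2
  dp <- .ld_from_D(D, EM / 2, EN / 2)$Dprime
  ld_value(r2 = r2, D = D, Dprime = dp)
}

#' Collapse phased pair counts to unphased dosage counts
#'
#' Each 4x4 cell maps to the dosage pair carried by its two haplotypes;
#' cells with the same dosage signature are summed. The double-heterozygote
#' dosage cell (1, 1) pools the coupling (00/11, 11/00) and repulsion
#' (01/10, 10/01) configurations, which is the information lost by
#' unphased data.
#'
#' @param pc A [pair_counts()] table.
#' @return A [dosage_sample()] with the same total n.
#' @export
pair_counts_to_dosage <- function(pc) {
  out <- matrix(0, 3, 3)
  for (i in 1:4) {
    for (j in 1:4) {
      dm <- .CELL_DOSAGE_M[i, j]
      dn <- .CELL_DOSAGE_N[i, j]
      out[dm + 1L, dn + 1L] <- out[dm + 1L, dn + 1L] + pc[i, j]
    }
  }
  dosage_sample(out)
}
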