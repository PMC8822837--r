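# Domain containers shared across the package.
#
# Haplotypes at two biallelic loci (M, N) are labelled "00", "01", "10",
# "11": first digit = allele at M, second = allele at N, alleles coded 0/1.
# Throughout, index order is c("00", "01", "10", "11").

.HAP_LABELS <- c("00", "01", "10", "11")
.ALLELE_M <- c(0, 0, 1, 1)  # allele at locus M carried by haplotype k
.ALLELE_N <- c(0, 1, 0, 1)  # allele at locus N carried by haplotype k
.SUM_TOL <- 1e-12

#' Haplotype frequencies of one parental line
#'
#' Container for the four haplotype frequencies of a single line at two
#' biallelic loci, in the fixed order 00, 01, 10, 11 (alleles at loci M, N).
#'
#' @param f00,f01,f10,f11 Haplotype frequencies; must be in \[0, 1\] and sum
#'   to 1 (tolerance 1e-12). A length-4 numeric vector may be passed as
#'   `f00` instead.
#' @return A named numeric vector of class `"line_hap_freqs"`.
#' @examples
#' h <- line_hap_freqs(0.4, 0.1, 0.1, 0.4)
#' hap_marginals(h)  # allele-1 frequencies at M and N
#' @export
line_hap_freqs <- function(f00, f01 = NULL, f10 = NULL, f11 = NULL) {
  if (is.null(f01) && length(f00) == 4L) {
    f <- as.numeric(f00)
  } else {
    f <- c(f00, f01, f10, f11)
  }
  if (length(f) != 4L || anyNA(f)) {
    stop("haplotype frequencies must be 4 non-missing numbers", call. = FALSE)
  }
  if (any(f < -.SUM_TOL) || any(f > 1 + .SUM_TOL)) {
    stop("haplotype frequencies must lie in [0, 1]", call. = FALSE)
  }
  if (abs(sum(f) - 1) > .SUM_TOL) {
    stop(sprintf("haplotype frequencies must sum to 1 (got %.15g)", sum(f)),
         call. = FALSE)
  }
  f <- pmin(pmax(f, 0), 1)
  names(f) <- .HAP_LABELS
  structure(f, class = "line_hap_freqs")
}

#' @export
print.line_hap_freqs <- function(x, ...) {
  cat("Line haplotype frequencies (loci M, N):\n")
  print(unclass(x), ...)
  m <- hap_marginals(x)
  cat(sprintf("allele-1 frequencies: pM = %.6g, pN = %.6g\n", m[1], m[2]))
  invisible(x)
}

#' Marginal allele-1 frequencies of a haplotype-frequency set
#'
#' @param h A [line_hap_freqs()] object (or plain length-4 vector in the
#'   canonical order).
#' @return Named numeric vector `c(pM =, pN =)`.
#' @export
hap_marginals <- function(h) {
  c(pM = unname(h[3] + h[4]), pN = unname(h[2] + h[4]))
}

#' A set of LD measures for one pair of loci
#'
#' Bundles the squared correlation `r2`, gametic covariance `D`, and
#' Lewontin-normalised `Dprime`, with a `defined` flag that is `FALSE` when
#' a locus is monomorphic (all three measures are then `NA`).
#'
#' @param r2,D,Dprime Numeric scalars.
#' @param defined Logical; `FALSE` marks an undefined value (monomorphic
#'   locus or zero dosage variance).
#' @return A list of class `"ld_value"`.
#' @export
ld_value <- function(r2, D, Dprime, defined = TRUE) {
  if (!defined) {
    r2 <- D <- Dprime <- NA_real_
  }
  structure(list(r2 = r2, D = D, Dprime = Dprime, defined = defined),
            class = "ld_value")
}

#' @export
print.ld_value <- function(x, ...) {
  if (!x$defined) {
    cat("LD value: undefined (monomorphic locus or zero variance)\n")
  } else {
    cat(sprintf("LD value: r2 = %.6g, D = %.6g, D' = %.6g\n",
                x$r2, x$D, x$Dprime))
  }
  invisible(x)
}

#' Ordered haplotype-pair counts for a crossbred sample
#'
#' The sufficient statistic for both LD estimators: a 4x4 table of counts
#' where cell (i, j) is the number of crossbred individuals that carry
#' line-A haplotype i and line-B haplotype j (i, j in 00, 01, 10, 11).
#' Row margins are the line-A haplotype counts, column margins the line-B
#' counts.
#'
#' @param counts 4x4 matrix of non-negative integer counts; rows = line-A
#'   haplotype, columns = line-B haplotype, both in canonical order.
#' @return A matrix of class `"pair_counts"` with attribute `n` (total
#'   individuals).
#' @export
pair_counts <- function(counts) {
  counts <- as.matrix(counts)
  if (!all(dim(counts) == c(4L, 4L))) {
    stop("pair counts must be a 4x4 matrix", call. = FALSE)
  }
  if (anyNA(counts) || any(counts < 0) || any(counts != round(counts))) {
    stop("pair counts must be non-negative integers", call. = FALSE)
  }
  storage.mode(counts) <- "double"
  dimnames(counts) <- list(line_A = .HAP_LABELS, line_B = .HAP_LABELS)
  structure(counts, n = sum(counts), class = c("pair_counts", "matrix"))
}

#' @export
print.pair_counts <- function(x, ...) {
  cat(sprintf("Crossbred haplotype-pair counts (n = %d individuals):\n",
              as.integer(attr(x, "n"))))
  y <- x
  attributes(y) <- attributes(x)[c("dim", "dimnames")]
  print(y, ...)
  invisible(x)
}

#' Unphased genotype-dosage counts for a crossbred sample
#'
#' A 3x3 table of counts over dosage pairs: rows = dosage (0/1/2) of allele
#' 1 at locus M, columns = dosage at locus N. This is what remains of a
#' [pair_counts()] table once phase is discarded: the double-heterozygote
#' cell (1, 1) pools coupling (00/11) and repulsion (01/10) configurations.
#'
#' @param counts 3x3 matrix of non-negative integer counts.
#' @return A matrix of class `"dosage_sample"` with attribute `n`.
#' @export
dosage_sample <- function(counts) {
  counts <- as.matrix(counts)
  if (!all(dim(counts) == c(3L, 3L))) {
    stop("dosage counts must be a 3x3 matrix", call. = FALSE)
  }
  if (anyNA(counts) || any(counts < 0) || any(counts != round(counts))) {
    stop("dosage counts must be non-negative integers", call. = FALSE)
  }
  storage.mode(counts) <- "double"
  dimnames(counts) <- list(dosage_M = 0:2, dosage_N = 0:2)
  structure(counts, n = sum(counts), class = c("dosage_sample", "matrix"))
}

#' @export
print.dosage_sample <- function(x, ...) {
  cat(sprintf("Crossbred genotype-dosage counts (n = %d individuals):\n",
              as.integer(attr(x, "n"))))
  y <- x
  attributes(y) <- attributes(x)[c("dim", "dimnames")]
  print(y, ...)
  invisible(x)
}
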