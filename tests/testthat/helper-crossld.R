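# Shared test helpers: random valid inputs and brute-force oracles.

# Random haplotype-frequency set with both loci comfortably polymorphic.
rand_hap <- function() {
  repeat {
    f <- stats::runif(4)
    h <- line_hap_freqs(f / sum(f))
    m <- hap_marginals(h)
    if (all(m > 0.02 & m < 0.98)) return(h)
  }
}

# Brute-force crossbred LD oracle: enumerate the 16-cell joint
# distribution of (line-A hap, line-B hap), form the dosage pair carried
# by each cell, and compute the dosage correlation from first principles.
# Independent of both closed-form routes in the package.
oracle_crossbred_r2 <- function(hA, hB) {
  tab <- outer(as.numeric(hA), as.numeric(hB))
  aM <- c(0, 0, 1, 1)
  aN <- c(0, 1, 0, 1)
  dM <- outer(aM, aM, `+`)
  dN <- outer(aN, aN, `+`)
  EM <- sum(tab * dM); EN <- sum(tab * dN)
  EM2 <- sum(tab * dM^2); EN2 <- sum(tab * dN^2)
  EMN <- sum(tab * dM * dN)
  (EMN - EM * EN)^2 / ((EM2 - EM^2) * (EN2 - EN^2))
}

# Same enumeration, returning all five dosage moments (oracle for
# dosage_moments()).
oracle_dosage_moments <- function(hA, hB) {
  tab <- outer(as.numeric(hA), as.numeric(hB))
  aM <- c(0, 0, 1, 1)
  aN <- c(0, 1, 0, 1)
  dM <- outer(aM, aM, `+`)
  dN <- outer(aN, aN, `+`)
  list(E_Mg = sum(tab * dM), E_Ng = sum(tab * dN),
       E_Mg2 = sum(tab * dM^2), E_Ng2 = sum(tab * dN^2),
       E_MgNg = sum(tab * dM * dN))
}

# Expand a dosage_sample to per-individual dosage vectors (for Pearson
# oracles via stats::cor).
expand_dosages <- function(ds) {
  idx <- which(unclass(ds) >= 0, arr.ind = TRUE)
  reps <- as.vector(unclass(ds))
  data.frame(m = rep(idx[, 1] - 1, reps), n = rep(idx[, 2] - 1, reps))
}
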