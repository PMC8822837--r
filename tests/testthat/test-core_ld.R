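# Closed-form population quantities: allele frequencies, inbreeding,
# haplotype construction, and the two routes to the crossbred r2.

test_that("crossbred allele frequency is the average of the line frequencies", {
  expect_equal(crossbred_allele_freq(0.05, 0.09), 0.07)
  expect_equal(crossbred_allele_freq(0.3, 0.3), 0.3)
  expect_equal(crossbred_allele_freq(0, 1), 0.5)
  expect_error(crossbred_allele_freq(-0.1, 0.5), "probability")
})

test_that("inbreeding coefficient solves the HW-departure relation", {
  # oracle: the defining relation pA*pB = p^2 + p(1-p) f, solved by hand
  expect_equal(inbreeding_coefficient(0.05, 0.09),
               (0.05 * 0.09 - 0.07^2) / (0.07 * 0.93))
  expect_equal(inbreeding_coefficient(0.25, 0.29),
               (0.25 * 0.29 - 0.27^2) / (0.27 * 0.73))
  expect_equal(inbreeding_coefficient(0.3, 0.3), 0)
  expect_error(inbreeding_coefficient(0, 0), "monomorphic")
  expect_error(inbreeding_coefficient(1, 1), "monomorphic")
})

test_that("inbreeding coefficient is never positive, zero iff equal lines", {
  set.seed(42)
  for (k in 1:200) {
    p <- runif(2, 0.01, 0.99)
    f <- inbreeding_coefficient(p[1], p[2])
    expect_lte(f, 0)
    if (abs(p[1] - p[2]) > 1e-12) expect_lt(f, 0)
  }
})

test_that("legacy printed inbreeding variant reproduces its published values", {
  expect_equal(signif(inbreeding_coefficient_printed(0.05, 0.09), 2), -0.0056)
  expect_equal(signif(inbreeding_coefficient_printed(0.25, 0.29), 2), -0.0015)
  expect_equal(inbreeding_coefficient_printed(0.3, 0.3), 0)
  # it differs from the derivation-consistent form whenever pA != pB
  expect_false(isTRUE(all.equal(inbreeding_coefficient_printed(0.05, 0.09),
                                inbreeding_coefficient(0.05, 0.09))))
})

test_that("f_M = f_N only in degenerate configurations", {
  # random search: equality of the two per-locus inbreeding coefficients
  # is a measure-zero event away from the trivial solutions
  set.seed(7)
  hits <- 0L
  for (k in 1:5000) {
    p <- runif(4, 0.01, 0.99)  # pAM, pBM, pAN, pBN
    if (abs(p[1] - p[2]) < 0.01 || abs(p[3] - p[4]) < 0.01) next
    fM <- inbreeding_coefficient(p[1], p[2])
    fN <- inbreeding_coefficient(p[3], p[4])
    if (abs(fM - fN) < 1e-12) hits <- hits + 1L
  }
  expect_identical(hits, 0L)
  # trivial solution: equal frequencies at both loci
  expect_equal(inbreeding_coefficient(0.2, 0.2),
               inbreeding_coefficient(0.4, 0.4))
})

test_that("d_bounds gives the standard feasibility rectangle", {
  expect_equal(d_bounds(0.5, 0.5), c(Dmin = -0.25, Dmax = 0.25))
  expect_equal(d_bounds(0.05, 0.05), c(Dmin = -0.0025, Dmax = 0.0475))
  expect_equal(d_bounds(0.45, 0.45), c(Dmin = -0.2025, Dmax = 0.2475))
  expect_error(d_bounds(0, 0.5), "monomorphic")
})

test_that("hap_freqs_from_params builds frequencies that round-trip", {
  expect_equal(as.numeric(hap_freqs_from_params(0.5, 0.5, 1)),
               c(0.5, 0, 0, 0.5))
  expect_equal(as.numeric(hap_freqs_from_params(0.5, 0.5, 0)),
               rep(0.25, 4))
  h <- hap_freqs_from_params(0.45, 0.45, 0.2)
  expect_equal(unname(h[4]), 0.2025 + sqrt(0.2) * 0.2475)
  # round-trip property over random feasible parameter sets
  set.seed(11)
  for (k in 1:100) {
    pM <- runif(1, 0.05, 0.95)
    pN <- runif(1, 0.05, 0.95)
    phase <- sample(c(-1, 1), 1)
    b <- d_bounds(pM, pN)
    dcap <- if (phase > 0) b["Dmax"] else -b["Dmin"]
    r2max <- dcap^2 / (pM * (1 - pM) * pN * (1 - pN))
    r2 <- runif(1, 0, r2max)
    h <- hap_freqs_from_params(pM, pN, r2, phase)
    ld <- line_ld(h)
    m <- hap_marginals(h)
    expect_equal(unname(m["pM"]), pM, tolerance = 1e-12)
    expect_equal(unname(m["pN"]), pN, tolerance = 1e-12)
    expect_equal(ld$r2, r2, tolerance = 1e-12)
    if (r2 > 1e-10) expect_equal(sign(ld$D), phase)
  }
})

test_that("infeasible r2 is rejected with the admissible maximum named", {
  expect_error(hap_freqs_from_params(0.05, 0.45, 0.9),
               "max feasible r2")
  expect_error(hap_freqs_from_params(0.05, 0.05, 0.5, phase = -1),
               "infeasible")
})

test_that("line_ld computes D, r2 and Lewontin D'", {
  eq <- line_ld(line_hap_freqs(0.25, 0.25, 0.25, 0.25))
  expect_equal(eq$D, 0)
  expect_equal(eq$r2, 0)
  expect_equal(eq$Dprime, 0)
  perfect <- line_ld(line_hap_freqs(0.5, 0, 0, 0.5))
  expect_equal(perfect$D, 0.25)
  expect_equal(perfect$r2, 1)
  expect_equal(perfect$Dprime, 1)
  mid <- line_ld(line_hap_freqs(0.4, 0.1, 0.1, 0.4))
  expect_equal(mid$D, 0.15)
  expect_equal(mid$r2, 0.36)
  # monomorphic locus: flagged, not an error
  mono <- line_ld(line_hap_freqs(0.5, 0.5, 0, 0))
  expect_false(mono$defined)
  expect_true(is.na(mono$r2))
  # |D'| <= 1 and r2 = 0 iff D = 0 on random inputs
  set.seed(5)
  for (k in 1:100) {
    ld <- line_ld(rand_hap())
    expect_lte(abs(ld$Dprime), 1 + 1e-12)
    expect_identical(ld$r2 == 0, ld$D == 0)
  }
})

test_that("crossbred_true_ld: identical lines reduce to within-line LD", {
  set.seed(3)
  for (k in 1:20) {
    h <- rand_hap()
    expect_equal(crossbred_true_ld(h, h)$r2, line_ld(h)$r2,
                 tolerance = 1e-12)
    expect_equal(crossbred_true_ld(h, h)$D, line_ld(h)$D,
                 tolerance = 1e-12)
  }
})

test_that("opposite-phase lines with equal variances cancel", {
  hA <- line_hap_freqs(0.4, 0.1, 0.1, 0.4)  # D = +0.15
  hB <- line_hap_freqs(0.1, 0.4, 0.4, 0.1)  # D = -0.15, same margins
  ld <- crossbred_true_ld(hA, hB)
  expect_equal(ld$r2, 0)
  expect_equal(ld$D, 0)
})

test_that("haplotype route agrees with the enumeration oracle", {
  hA <- hap_freqs_from_params(0.05, 0.05, 0.2)
  hB <- hap_freqs_from_params(0.45, 0.45, 0.2)
  expect_equal(crossbred_true_ld(hA, hB)$r2, oracle_crossbred_r2(hA, hB),
               tolerance = 1e-12)
  set.seed(21)
  for (k in 1:50) {
    hA <- rand_hap(); hB <- rand_hap()
    expect_equal(crossbred_true_ld(hA, hB)$r2, oracle_crossbred_r2(hA, hB),
                 tolerance = 1e-12)
  }
})

test_that("crossbred genotype-frequency table is a valid joint distribution", {
  set.seed(13)
  for (k in 1:50) {
    hA <- rand_hap(); hB <- rand_hap()
    tab <- crossbred_genotype_freqs(hA, hB)
    expect_true(all(tab >= 0))
    expect_equal(sum(tab), 1, tolerance = 1e-12)
    expect_equal(unname(rowSums(tab)), unname(as.numeric(hA)),
                 tolerance = 1e-12)
    expect_equal(unname(colSums(tab)), unname(as.numeric(hB)),
                 tolerance = 1e-12)
    # cell (11, 00) = u * r'
    expect_equal(unname(tab["11", "00"]),
                 unname(hA[4] * hB[1]), tolerance = 1e-15)
  }
  expect_equal(unname(crossbred_genotype_freqs(
    line_hap_freqs(rep(0.25, 4)), line_hap_freqs(rep(0.25, 4)))),
    matrix(0.0625, 4, 4))
})

test_that("dosage moments match the brute-force enumeration to 1e-14", {
  h <- line_hap_freqs(0.5, 0, 0, 0.5)
  m <- dosage_moments(h, h)
  expect_equal(m$E_Mg, 1)
  expect_equal(m$E_Mg2, 1.5)
  expect_equal(m$E_MgNg, 1.5)
  u <- line_hap_freqs(rep(0.25, 4))
  expect_equal(dosage_moments(u, u)$E_MgNg, 1)
  set.seed(17)
  for (k in 1:200) {
    hA <- rand_hap(); hB <- rand_hap()
    m <- dosage_moments(hA, hB)
    o <- oracle_dosage_moments(hA, hB)
    for (nm in names(o)) {
      expect_equal(m[[nm]], o[[nm]], tolerance = 1e-14)
    }
    # moment sanity: E(X^2) >= E(X)^2, dosage means = pA + pB
    mA <- hap_marginals(hA); mB <- hap_marginals(hB)
    expect_equal(m$E_Mg, unname(mA["pM"] + mB["pM"]), tolerance = 1e-14)
    expect_gte(m$E_Mg2, m$E_Mg^2)
    expect_gte(m$E_Ng2, m$E_Ng^2)
  }
})

test_that("equivalence theorem: Eq-1 and Eq-2 routes agree to 1e-12", {
  h <- line_hap_freqs(0.5, 0, 0, 0.5)
  expect_equal(crossbred_r2_from_moments(dosage_moments(h, h))$r2, 1)
  u <- line_hap_freqs(rep(0.25, 4))
  expect_equal(crossbred_r2_from_moments(dosage_moments(u, u))$r2, 0)
  set.seed(23)
  for (k in 1:300) {
    hA <- rand_hap(); hB <- rand_hap()
    r2_hap <- crossbred_true_ld(hA, hB)$r2
    r2_geno <- crossbred_r2_from_moments(dosage_moments(hA, hB))$r2
    expect_lt(abs(r2_hap - r2_geno), 1e-12)
    # the D measures (Eq-1 and Eq-2 numerator roots) are identical too
    expect_lt(abs(crossbred_true_ld(hA, hB)$D -
                    crossbred_r2_from_moments(dosage_moments(hA, hB))$D),
              1e-12)
  }
})

test_that("zero dosage variance is flagged undefined", {
  h <- line_hap_freqs(1, 0, 0, 0)
  m <- dosage_moments(h, h)
  res <- crossbred_r2_from_moments(m)
  expect_false(res$defined)
  expect_false(crossbred_true_ld(h, h)$defined)
})
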