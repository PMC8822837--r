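---
title: "Linkage disequilibrium in crossbred populations: model, estimators, simulation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Linkage disequilibrium in crossbred populations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(crossLD)
```

## The problem

Linkage disequilibrium (LD) between two biallelic loci is usually measured
as the squared correlation $r^2$ between the alleles carried on
haplotypes. When haplotypes are unknown, $r^2$ can instead be estimated as
the squared Pearson correlation between the unphased genotype dosages
(0/1/2) at the two loci, the Rogers–Huff approach. The classical
justification of that shortcut assumes equal parental allele frequencies
and a common inbreeding coefficient at the two loci. An F1 crossbred
population — every individual carries one haplotype from line $A$ and one
from line $B$, lines mated at random — violates both assumptions: its
inbreeding coefficients are *negative* (heterozygote excess) and typically
differ between loci.

`crossLD` implements the population theory showing that the dosage-based
$r^2$ nevertheless has exactly the haplotype-based $r^2$ as its
expectation in an F1 cross, the two corresponding sample estimators, and
a Monte-Carlo machinery that quantifies their bias and precision.

## Model

### Crossbred inbreeding coefficients

With allele-1 frequencies $p_{AM}$, $p_{BM}$ at locus $M$, the crossbred
frequency is $p_M = (p_{AM}+p_{BM})/2$ and the genotype-11 frequency under
random line-crossing is $p_{AM}p_{BM}$. The Hardy–Weinberg departure
$f_M$ is defined by
$$p_{AM}p_{BM} = p_M^2 + p_M(1-p_M)f_M,$$
which solves to
$$f_M = \frac{-(p_{AM}-p_{BM})^2}{(p_{AM}+p_{BM})(2-p_{AM}-p_{BM})} \le 0 ,$$
with equality iff $p_{AM}=p_{BM}$ (`inbreeding_coefficient()`). A variant
with denominator $(p_{AM}+p_{BM})(2-p_{AM}+p_{BM})$ circulates in print;
it is inconsistent with the defining relation above (the sign of the last
$p_{BM}$ differs) but is retained verbatim as
`inbreeding_coefficient_printed()` because published worked examples
($f_M=-0.0056$, $f_N=-0.0015$ for frequencies 0.05/0.09 and 0.25/0.29)
evaluate the printed form. The derivation-consistent form is the package
default; $f$ plays no role in the $r^2$ theory below, so nothing
downstream depends on the choice.

A numeric search (test suite) confirms that $f_M = f_N$ essentially only
in degenerate configurations (equal line frequencies, fixed alleles), so
the classical equal-$f$ justification of dosage correlation genuinely does
not apply to crossbreds.

### Two routes to the crossbred $r^2$

Write the line-$A$ haplotype frequencies at loci $(M,N)$ as
$f_{00},f_{01},f_{10},f_{11}$ (allele order $M$ then $N$), with marginals
$p_M = f_{10}+f_{11}$, $p_N = f_{01}+f_{11}$, and similarly primed for
line $B$. Within a line, $D = f_{11}-p_Mp_N$ and allele counts on one
haplotype are Bernoulli, so the variances are $p(1-p)$.

**Haplotype route** (`crossbred_true_ld()`). A crossbred genotype is the
sum of one line-$A$ and one line-$B$ haplotype, drawn independently, so
the crossbred covariance between loci is the *average* of the per-line
covariances and the per-locus variance is the average of the per-line
variances:
$$r^2 \;=\; \frac{(D_A+D_B)^2}{\left(v_{NA}+v_{NB}\right)\left(v_{MA}+v_{MB}\right)},$$
the factors $2^2$ from averaging cancelling between numerator and
denominator. The crossbred $D$ is $(D_A+D_B)/2$.

**Genotype route** (`dosage_moments()` +
`crossbred_r2_from_moments()`). From the $4\times4$ table of crossbred
genotype frequencies $h_{A,i}\,h_{B,j}$ (`crossbred_genotype_freqs()`)
one obtains closed forms for the dosage moments, e.g.
$E(M_g) = (f_{10}+f_{11}) + (f'_{10}+f'_{11})$ and
$E(M_g^2) = E(M_g) + 2(f'_{10}+f'_{11})(f_{10}+f_{11})$, and then
$r^2 = \mathrm{cov}(M_g,N_g)^2/(\mathrm{var}(M_g)\,\mathrm{var}(N_g))$.

Expanding the moments shows the two routes are *algebraically identical*,
irrespective of the (unequal, negative) inbreeding coefficients. The test
suite verifies agreement to $10^{-12}$ on thousands of random frequency
sets, and the same equivalence holds for $D$ (the numerators). $D'$ is
not determined by the equivalence argument; the package uses the Lewontin
normalisation ($D/D_{\max}$ for $D\ge0$, $D/|D_{\min}|$ otherwise)
evaluated at the crossbred average allele frequencies, a deliberate
convention choice.

```{r}
hA <- hap_freqs_from_params(0.05, 0.05, r2 = 0.2)
hB <- hap_freqs_from_params(0.45, 0.45, r2 = 0.2)
crossbred_true_ld(hA, hB)
crossbred_r2_from_moments(dosage_moments(hA, hB))
```

### Estimators

Both estimators consume the $4\times4$ table of ordered
(line-$A$ haplotype, line-$B$ haplotype) counts (`pair_counts()`), the
sufficient statistic of a phased crossbred sample.

* `estimate_ld_haplotype()` substitutes the per-line sample haplotype
  frequencies (row and column margins) into the haplotype-route formula.
  The per-line plug-in form is deliberate: pooling the $2n$ haplotypes of
  both lines adds a between-line covariance term
  $(p_{MA}-p_{MB})(p_{NA}-p_{NB})/4$ to $D$ and therefore estimates a
  different target when line frequencies differ at both loci. The pooled
  variant remains available (`pooled = TRUE`) and is tested to show
  exactly that shift.
* `estimate_ld_genotype()` discards phase
  (`pair_counts_to_dosage()` — the double-heterozygote cell pools the
  coupling 00/11 and repulsion 01/10 configurations) and squares the
  sample Pearson correlation of the dosages. Moments use the
  population-style $n$ denominator; $r^2$ is invariant to $n$ vs $n-1$.

The information gap between the two is exactly the coupling/repulsion
split of double heterozygotes: swapping counts between the (00,11) and
(01,10) cells leaves the genotype estimate unchanged while moving the
haplotype estimate.

Degenerate inputs are signalled, not silently zeroed: population formulas
raise an error on a monomorphic crossbred locus, estimators return
`defined = FALSE`. Definedness is evaluated at the *crossbred* level — a
sample in which one line is monomorphic at a locus but the cross is not
still has a well-defined $r^2$.

## The simulator's stated world

`build_scenario_grid()` reproduces the reference simulation design:
allele-frequency levels $\{0.05, 0.15, 0.25, 0.35, 0.45\}$ as unordered
line pairs (15 combinations; frequencies equal at both loci within a
line), within-line $r^2 \in \{0.2, 0.4, 0.6, 0.8\}$ (equal in both
lines, coupling phase), crossbred sample sizes $\{900, 1800, 2700\}$ —
180 scenarios, 1000 replicates each. Phase is a free sign parameter
(`phase`), defaulting to coupling ($D>0$); $r^2$ results are invariant to
a common sign flip.

Sampling: a crossbred sample of $n$ individuals is one multinomial draw
over the 16 ordered haplotype-pair categories with probabilities
$h_{A,i}h_{B,j}$ — provably the same distribution as sampling $n$
haplotypes per line and pairing at random (kept as the slow `"pairing"`
reference sampler and checked distributionally), but fast enough that the
whole 180-scenario study runs in about a second. Seeds: a master seed is
expanded into per-scenario seeds by a counter-based rule
(`crossLD:::derive_seed`), so scenarios are independent and individually
re-runnable; every pipeline output is bit-reproducible from its recorded
seed. Replicates in which either estimator is undefined are excluded from
summaries and counted; at the grid's scales they essentially never occur
(minor haplotype count $\approx n \cdot 0.0025 \gg 0$ at worst).

What the generator does *not* emulate: genotyping or phasing error,
linkage between more than two loci, selection, non-random mating between
the lines, and finite parental population structure (the lines are
infinite haplotype pools). A green Monte-Carlo test therefore establishes
properties of the estimators under ideal phased data, not robustness to
real-data artefacts.

`summarize_scenario()` reports per-estimator mean, bias, SD ($n-1$
denominator, the standard choice for reporting estimator precision), the
ratio of precision $\mathrm{SD}_{hap}/\mathrm{SD}_{geno}$ (below 1 =
haplotype route more precise), and two-sided one-sample t-test p-values
against the true $r^2$. The "independent sample t-test" of the reference
description is against a known constant, which is not an
independent-sample design; the one-sample form is the faithful
implementation of "test the bias from the true value", and a Welch
two-sample variant (`compare_estimators_test()`) is provided for
hap-vs-geno comparisons. P-values are reported raw, uncorrected across
scenarios.

## Numerical choices

* Closed-form identities tested at $10^{-12}$ absolute; probability sums
  at $10^{-12}$; moment-vs-enumeration oracles at $10^{-14}$.
* `hap_freqs_from_params()` rejects infeasible $(p, r^2)$ combinations at
  construction time, naming the admissible maximum $r^2$ (from the
  standard $D$ bounds, `d_bounds()`); grid construction therefore fails
  fast rather than producing invalid scenarios.
* Tie-break in $D'$: $D = 0$ gives $D' = 0$.
* All randomness flows through R's default RNG, seeded explicitly;
  vectorised and per-replicate execution paths are tested to produce
  identical numbers.

## Known limitations

* **Small-sample bias direction.** At $n \le 300$ the replicate-mean bias
  of both estimators in this generator's world is predominantly
  *positive* (up to $+0.02$ at MAF 0.05, $n=100$), largest at low $r^2$
  and low MAF — consistent with the classical approximation
  $\mathrm{bias}(\hat r^2) \approx (1-r^2)(1-2r^2)/n$, which is positive
  for $r^2<0.5$. Reference results describing a small *downward* bias at
  these sample sizes do not reproduce here; the corresponding acceptance
  assertion is deliberately left failing rather than inverted. At the
  main grid's scales ($n \ge 900$) both estimators are unbiased within
  Monte-Carlo noise, which is the substantive conclusion.
* Two loci, two lines, biallelic only. Other cross types (F2, Fn, BC)
  are reachable by re-parameterising the line inputs, not modelled
  explicitly.
* The haplotype estimator assumes error-free phase; with estimated
  haplotypes its precision advantage shrinks.
* VCF input is deliberately minimal (two biallelic sites, GT only);
  genome-wide scans are out of scope.
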