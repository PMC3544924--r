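---
title: "Gene-set variance-component association testing with cgsa"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Gene-set variance-component association testing with cgsa}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cgsa)
```

## The model

Single-marker candidate-gene tests examine one SNP at a time and pay a
heavy price when a trait is shaped by many loci of modest effect scattered
over a functionally related group of genes — a signalling pathway, a
regulatory network, a set of genes under related QTL. `cgsa` implements a
candidate *gene-set* association test: all SNPs assigned to the set are
summarised into relationship kernels, and the set's joint contribution to a
quantitative trait is estimated and tested as a variance component in a
mixed linear model,

$$
\mathbf{y} = \mathbf{X}\mathbf{b} + \mathbf{a} + \mathbf{d} +
\mathbf{i}_{aa} + \mathbf{i}_{ad} + \mathbf{i}_{dd} + \mathbf{e},
$$

where $\mathbf{b}$ holds fixed effects (intercept plus categorical
covariates such as gender and sire, factor-coded with first-level reference
dropping), and the random terms are the set-level additive, dominance, and
additive-by-additive / additive-by-dominance / dominance-by-dominance
epistatic genetic values with

$$
\mathbf{a} \sim \mathrm{MVN}(\mathbf{0}, \sigma^2_a \mathbf{A}), \quad
\mathbf{d} \sim \mathrm{MVN}(\mathbf{0}, \sigma^2_d \mathbf{D}), \quad
\mathbf{i}_{aa} \sim \mathrm{MVN}(\mathbf{0}, \sigma^2_{aa}
\mathbf{A}\!\circ\!\mathbf{A}),
$$

and so on, with $\mathbf{e} \sim \mathrm{MVN}(\mathbf{0}, \sigma^2_e
\mathbf{I})$. With one record per individual every random-effect design
matrix is the identity, so the kernels enter directly as $n \times n$
matrices; repeated measures are out of scope.

### Kernels from identity-by-descent sharing

The additive and dominance matrices are built from pairwise
identity-by-descent (IBD) probabilities estimated from the gene-set SNPs by
the PLINK-style method of moments: observed identity-by-state (IBS) 0/1/2
counts across SNPs are equated to their expectations given in-sample allele
frequencies, and the triangular system is inverted to $\hat P_0, \hat P_1,
\hat P_2$. Each estimate is truncated to $[0,1]$ *before* it enters the
next moment equation (the bounded behaviour of the original software) and
the triple is renormalised onto the simplex. Then

$$
A_{ij} = \hat P_2(i,j) + \tfrac12 \hat P_1(i,j) = \hat\pi_{ij}, \qquad
D_{ij} = \hat P_2(i,j),
$$

with the self-relationship convention $A_{ii} = D_{ii} = 1$ (pairwise IBD
output has no self terms; the target populations are outbred hybrids, so
inbreeding is ignored — the diagonal is configurable). The three epistatic
kernels are Hadamard (elementwise) products: $\mathbf{A}\!\circ\!\mathbf{A}$,
$\mathbf{A}\!\circ\!\mathbf{D}$, $\mathbf{D}\!\circ\!\mathbf{D}$.

Missing genotypes are handled pairwise-complete: each pair's moment
equations use only the SNPs observed in both individuals, and pairs with
fewer informative SNPs than `min_informative` (default 10) are flagged
low-confidence. Allele frequencies are always estimated in-sample; no
reference panel is consulted. Monomorphic SNPs carry no IBS information and
are skipped with a warning. A VanRaden-style genomic relationship matrix is
deliberately *not* offered as the default, to keep the kernel definition
exactly the IBD-sharing one.

### REML estimation

Variance components are estimated by restricted maximum likelihood under
the non-negativity constraint $\sigma^2_k \ge 0$. Two code paths share one
likelihood definition:

* **Single kernel.** The kernel is eigendecomposed once; the restricted
  likelihood is profiled over the variance ratio
  $\delta = \sigma^2_k/\sigma^2_e$, making each evaluation $O(n)$. A coarse
  grid on $\log\delta \in [-12, 10]$ locates the basin, golden-section
  refinement polishes it, and the boundary $\delta = 0$ (the residual-only
  closed form) is always a candidate. The decomposition can be precomputed
  and amortised across thousands of fits on the same panel — this is what
  makes the replicate studies cheap.
* **Several kernels.** Bounded quasi-Newton (L-BFGS-B) on log-variances,
  run from three spread-out starts plus a start at the residual-only
  solution with all kernel variances at the numerical floor. The extra
  start guarantees in practice that adding a kernel never decreases the
  reported restricted log-likelihood (the test suite enforces agreement
  within $10^{-6}$). Components that finish at the floor are snapped to
  exactly zero.

Method-of-moments relationship matrices need not be positive semidefinite
(ours routinely are not, on small SNP panels); every kernel is projected
onto the PSD cone by clamping negative eigenvalues at zero before entering
the covariance model, identically in both code paths, and the reported
likelihood refers to the projected kernels.

### Testing on the boundary

A variance component tested against zero sits on the boundary of its
parameter space, so the likelihood-ratio statistic
$2(\ell_{\text{full}} - \ell_{\text{null}})$, floored at zero, is *not*
asymptotically $\chi^2_q$. `lrt()` uses the binomial-weighted boundary
mixture

$$
\sum_{k=0}^{q} \binom{q}{k} 2^{-q} \chi^2_k,
$$

which is $\tfrac12\chi^2_0 + \tfrac12\chi^2_1$ for one component. The
plain (conservative) $\chi^2_q$ reference is available via
`mixture = FALSE`. `test_gene_set()` wires the planned nested comparisons:
additive ($\{A\}$ vs. none), dominance given additive ($\{A,D\}$ vs.
$\{A\}$), and the joint epistatic block ($\{A,D,AA,AD,DD\}$ vs.
$\{A,D\}$, three components).

## What the simulator emulates — and what it does not

`simulate_genotypes()` draws unlinked biallelic SNPs under Hardy–Weinberg
equilibrium: per-SNP allele frequency uniform on `maf_range` (default
$[0.05, 0.5]$) and dosages $\mathrm{Binomial}(2, p)$. The default study
panel is 57 SNPs on 300 individuals — the shape of a single-pathway SNP
panel at a desk-scale sample size. What it deliberately does **not**
emulate: linkage disequilibrium between SNPs (real pathway SNPs cluster
within genes), allele-frequency ascertainment of commercial arrays, and
population structure or cryptic relatedness. Passing tests on this
generator therefore demonstrate calibration and relative power under clean
HWE conditions, not performance under LD or stratification.

The additive trait simulator draws per-QTN effects from $N(0,1)$ (redrawn
each replicate; a fixed effect vector can be supplied instead), computes
genetic values over the sampled QTNs, and scales the residual to the
*realized* additive variance so the trait attains its target heritability:
$\sigma^2_e = \sigma^2_a (1 - h^2)/h^2$. At $h^2 = 0$ that ratio is
undefined; we simulate pure $N(0,1)$ noise with no genetic term — the null
must be well defined for type-I-error estimation, and any positive residual
scale is equivalent because the tests are scale-equivariant (also verified
in the suite). The mixed-effects scenario adds dominance deviations
(indicator of heterozygosity) and epistatic pair effects expressed only
when an individual is heterozygous at *both* pair members; its shipped
effect table is a synthetic stand-in (additive $N(0,1)$, dominance
$N(0,0.5)$, pair effects of magnitude 1, drawn once and frozen) and any TSV
with the same columns can replace it.

## The power study and its baseline

`run_cgsa_power()` and `run_baseline_power()` share one seeding scheme —
the study seed fixes the QTN sample, and replicate $r$ simulates its trait
from seed $+ r$ — so the two methods are compared on identical phenotypes,
replicate by replicate. Power (or, at $h^2 = 0$, type-I error) is the
proportion of replicates significant at `alpha`, with the binomial standard
error reported.

The "traditional candidate gene approach" baseline is nowhere operationally
defined in the literature this package follows; this is the package's
biggest judgment call. We implement it as per-SNP linear-model tests of
each causal QTN (`trait ~ intercept + dosage`, plus any covariates) at the
*nominal* level with no multiplicity correction by default, scoring each
replicate by the proportion of QTNs detected. Both choices are exposed:
any `p.adjust` method can be applied within a replicate, and an "any-hit"
replicate score is available by flag. Under the default the baseline's
per-QTN type-I error is exactly nominal, which makes it a *generous*
comparator at very low heritability.

Default problem sizes are chosen for interactive desk-scale runs: 300
individuals, a 57-SNP panel, 500 replicates for calibration studies and
300 for power grids; the test suite and the acceptance script use these
sizes. Larger panels and replicate counts are plain arguments away.

## Co-localization conventions

All genomic coordinates are 1-based inclusive. A SNP is assigned to a gene
when it lies within the gene body extended by a 50 kb flank on each side
(inclusive boundaries, floored at position 1); a SNP can be assigned to
several overlapping windows. Gene–QTL co-localization defaults to nonempty
interval intersection; the stricter gene-contained-in-QTL mode ships as
`mode = "containment"` because "mapped to the confidence interval" can be
read either way, and the packaged FOXO3 table gives the same count (48)
under both. Co-localization uses the gene body only by default — the 50 kb
flank is documented for SNP-to-gene assignment, not for QTL matching. Very
wide QTL confidence intervals can swamp multiplicity counts, so a maximum
interval-width filter is available (off by default). Interval arithmetic is
delegated to `GenomicRanges`; BED export converts to 0-based half-open
coordinates.

The packaged QTL fixture carries no chromosome column in its source; all
48 records are fixed to chromosome 1 (the FOXO3 chromosome), as its header
documents. Chromosome labels are never coerced to numbers ("X" is a valid
label).

## Numerical choices and degenerate inputs

* Missing dosage is `NA_integer_`, an explicit sentinel — never a silent
  zero and never NaN arithmetic; kinship handles it pairwise-complete and
  trait simulation refuses QTN columns containing missing calls.
* Dosage counts the minor allele as computed from the file itself; a
  frequency-0.5 tie is broken toward the lexicographically smaller allele
  symbol, and a monomorphic SNP's counted allele is the unobserved one
  (all dosages 0, frequency 0 flags it). Round-tripping through the PLINK
  text writer is bit-exact for minor-allele-coded matrices.
* REML convergence: the profiled single-kernel search uses a $10^{-9}$
  interval tolerance; the multi-kernel quasi-Newton stops on a relative
  objective change of order $10^{-15}$ (factr = 10) with
  $10^{-6}$-scale numerical gradients, capped at 200 iterations; a
  non-converged fit is returned with its flag set, never silently.
* An LRT whose null log-likelihood exceeds the full model's by more than
  $10^{-6}$ raises a refit advisory error rather than reporting a negative
  statistic; a statistic of exactly zero yields $p = 1$.
* A kernel numerically indistinguishable from the identity triggers a
  warning naming it: its variance is confounded with the residual.
* Replicates excluded from a power study (failed fits) are counted and
  reported, with a warning above 1%; none occur under the default
  conditions.

## Known limitations

* The IBD moment estimator is biased upward on small SNP panels (the
  truncation at zero cannot average out); the mean off-diagonal $\hat\pi$
  shrinks toward zero only as the SNP count grows. Kernels built from a
  57-SNP set are noisy, which is partly why the set-level test's advantage
  over the single-SNP baseline is small at very low heritability and large
  at moderate heritability.
* No LD-aware genotype simulation, no BLUP of individual genetic values,
  no standard errors of variance components, and no multi-trait models.
* Real-data significance depends on the boundary-mixture choice; published
  pathway p-values obtained with other REML software are not reproduced
  here and are not a target.
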