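---
title: "Third-order linkage disequilibrium: model, estimation and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Third-order linkage disequilibrium: model, estimation and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ld3)
```

## The parameterization

Three biallelic loci define eight gametic haplotypes. `ld3` works in the
classical decomposition of their frequencies into three allele frequencies
(`f_T`, `f_M`, `f_K`, always of the *first-listed* allele of the input),
three pairwise coefficients (`d_TM`, `d_TK`, `d_MK`: two-locus haplotype
frequency minus the product of allele frequencies) and one third-order
coefficient `d_TMK`, the residual of the three-locus frequency after
removing the allele-frequency product and all pairwise terms:

$$f_{TMK} = f_T f_M f_K + f_T\,\delta_{MK} + f_M\,\delta_{TK}
          + f_K\,\delta_{TM} + \delta_{TMK}.$$

The other seven haplotype frequencies follow by alternating the sign of
each term with the allele index. Third-order LD is therefore an
association of one *allele* with a two-locus *haplotype*: at its positive
maximum (intermediate frequencies, zero pairwise LD,
$\delta_{TMK} = 1/8$) exactly the four haplotypes `TMK`, `tmK`, `Tmk`,
`tMk` segregate, none complementary to another.

Two facts shape everything downstream:

* **Bounds.** Each haplotype frequency is affine in `d_TMK` with slope
  $\pm 1$, so non-negativity of all eight gives a closed-form admissible
  interval (`delta3_bounds`). Globally $|\delta_{TMK}| \le 1/8$, and
  maximal pairwise LD (all $\delta = 1/4$ at intermediate frequencies)
  collapses the interval to the single point 0.
* **Orientation.** Relabeling the alleles at one locus negates `d_TMK`
  and the two pairwise coefficients involving that locus. Signs are
  meaningful only relative to the input's allele order (A1 in `.ped`,
  REF in VCF); the sign-flip rule is asserted as a package invariant.

## Normalization

`normalize_robinson()` rescales the observed `d_TMK` by the admissible
range *of its sign*: the excess over the minimum possible value of that
sign, divided by the length of the signed admissible range. Numerical
choices the literature leaves open:

* `tol = 1e-9` decides when the admissible range counts as a single point
  (category `undefined_single_value`) and when a value is classified as an
  endpoint (`plus_one`, `minus_one`, `zero`). No published tolerance
  exists; 1e-9 is far below any estimation noise and far above double
  rounding.
* When `d_TMK > 0` but the whole admissible interval is positive
  (`lower > 0`), the minimum possible of the positive sign is `lower`
  itself, so the range `[lower, upper]` is used unchanged (symmetrically
  for negative values).
* If the admissible range of the observed sign is empty — possible only
  through rounding at a boundary — the result is classified
  `undefined_single_value` rather than extrapolated.
* Negative values are reported signed (in `[-1, 0)`), so `-1` means "at
  the negative extreme".

Because tightly linked SNP triplets segregate few haplotypes, the
normalization degenerates to $\pm 1$, 0 or "single value" for most real
triplets; the proportion
$\beta_{TMK} = |\delta_{TMK}| / (|\delta_{TMK}|+|\delta_{TM}|+|\delta_{MK}|+|\delta_{TK}|)$
(`beta_proportion`) is offered as the robust alternative. With all four
coefficients zero, $\beta$ is undefined and returned as `NA` rather than
0: "no disequilibrium" and "no third-order share" are different
statements.

## Admixture

Crossing populations X and Y with mixing proportion $\tau$ averages every
haplotype frequency, which induces in the cross

$$\delta^Z = \tau\delta^X + (1-\tau)\delta^Y + \tau(1-\tau)\gamma\gamma'$$

for each pairwise coefficient ($\gamma$ = parental allele-frequency
difference), and a third-order coefficient that needs differences in
*both* allele frequencies and pairwise LD to be created from nothing.
`admix_closed_form()` implements the expanded expression;
`admix_via_haplotypes()` mixes the eight haplotype frequencies and
re-derives the decomposition. The two are algebraically identical and are
kept as mutually checking routes: any disagreement beyond 1e-10 fails the
build.

One wrinkle in the canonical nine-scenario illustration grid
(`admix_reference_table()`): two scenarios pair intermediate frequencies
with pairwise coefficients `(0.25, 0.25, 0)`, a combination that admits
**no** non-negative haplotype distribution (two implied frequencies are
$-1/8 \mp \delta_{TMK}$). The grid values for those rows are formal
algebraic evaluations, reproduced here with `validate = FALSE`; both
computation routes still agree exactly. Validation is on by default
everywhere else, so user-supplied infeasible parents are an error unless
explicitly waived.

## Recombination decay

Under random mating without interference, a gamete keeps its full
parental triplet with probability $(1-c_{TM})(1-c_{MK})$ and otherwise
splices marginal frequencies into the recombined intervals
(`next_generation`). Allele frequencies are conserved exactly; in the
symmetric case (intermediate frequencies, zero pairwise LD) third-order
LD decays *exactly* geometrically,
$\delta^t = [(1-c_{TM})(1-c_{MK})]^t\,\delta^0$, which the tests assert to
1e-12 over 100 generations. At $c = 0.001$ per interval (roughly 100 kb
at 1 cM/Mb — a documentation conversion only, never used in computation)
the 20-generation ratio is $0.999^{40} \approx 0.961$: tight linkage
preserves third-order LD almost indefinitely. The tensor is renormalized
by its sum each generation to stop float drift from accumulating over
very long trajectories ($10^4$ generations in the convergence test);
the correction is at machine precision per step. Recombination fractions
are capped at 0.5; interference, sex differences and overlapping
generations are out of scope. Genetic drift is deliberately *not* part of
the deterministic recursion: the finite-population counterpart lives in
`simulate_drift()`, which shares the same per-interval gamete rule.

## EM estimation

With unphased diploids, genotype triplets with two or more heterozygous
loci are phase-ambiguous. `em_fit()` iterates:

* **E-step**: each observed genotype cell distributes its count over the
  compatible ordered haplotype pairs in proportion to the current
  frequency products. This generic enumeration (at most 4 unordered pairs
  per cell) reproduces the classical coupling/repulsion `W` weights —
  exposed in `fit$ambiguity_weights` and asserted against the explicit
  formulas in the tests — while keeping the scheme extensible beyond
  three loci.
* **M-step**: gamete counting of the resolved expectations,
  $f^* = \text{expected copies}/2N$.

Numerical choices:

* Initialization is uniform (1/8). The likelihood is not concave in
  general, so `n_restarts` random (seeded) restarts are available;
  best log-likelihood wins. In practice the uniform start reaches the
  grid-search optimum on every tested dataset.
* Convergence: max absolute haplotype-frequency change `tol = 1e-8`,
  `max_iter = 10000`. On expected-count data this yields parameter error
  below 1e-7; non-convergence is reported, not raised.
* If an observed cell has probability zero under the current frequencies
  (possible only from pathological starts), its count is split equally
  across its compatible pairs for that step instead of creating an
  absorbing 0/0 state.
* The multinomial constant is omitted from all log-likelihoods; only
  differences matter.
* Missing data: complete cases per triplet (`counts_from_codes` drops
  individuals missing any of the three genotypes).
* Hardy–Weinberg equilibrium is assumed throughout; no inbreeding
  coefficient is fitted.

`lrt_independence()` contrasts the 7-parameter fit with the 3-parameter
product of observed allele frequencies. The chi-square(4) reference is an
inference from the parameter count — no canonical reference distribution
is established for this test — and the p-value is labeled nominal; under
a simulated independence null the empirical 95th percentile sits within a
few percent of 9.49. The third-order-only null (which would require
iterative proportional fitting) is intentionally not implemented: its
haplotype solutions are not maximum-likelihood and the parameter is often
range-degenerate.

## Scans

Three designs mirror common genome-scan practice: all consecutive-SNP
triplets per chromosome ($\sum(n_c - 2)$ records), random
inter-chromosomal triplets (three distinct chromosomes per draw, seeded),
and all triplets whose outermost members fit inside a rolling window of
`window_snps` consecutive SNPs (deduplicated by triplet identity, so each
qualifying triplet appears once; the count for width $w$ on $n$ SNPs is
the number of index triples with span $< w$). QC follows the usual
array conventions (`MAF > 0.05`, call rate `> 0.99`, thresholds
adjustable); triplets containing a monomorphic SNP are skipped with a
message because the EM is degenerate there. Coordinates are 1-based;
`span_bp` is the distance between the outermost SNPs. No multiple-testing
correction is applied; emitted p-values are nominal.

## What the synthetic generator does and does not emulate

`generate_panel()` models each chromosome as a shallow pool of founder
haplotypes — the situation of a composite livestock line founded from a
few strains — from which sample gametes descend as mosaics, switching
founders with a per-interval probability. Defaults: pool depth 8,
switch probability 0.05, mean SNP spacing 92.6 kb (a typical
medium-density array spacing), founder MAF in `[0.2, 0.5]`. Shallow pools
create strong multi-locus LD; mosaic switching makes it decay with
distance; chromosomes are generated independently, so inter-chromosomal
LD is zero in expectation. Cohort sizes in examples and tests use N = 306,
a realistic genotyped-herd size.

This emulates the *structure* that matters for the estimator — few
haplotypes per window, distance decay, unlinked chromosomes — not the
history of any real population: there is no coalescent, no mutation, no
selection, and founder haplotypes are i.i.d. across SNPs. A green scan
test therefore establishes that the estimator and scan machinery recover
the LD structure a pool-mosaic world generates at these sample sizes; it
does not validate demographic realism, nor reproduce any published
population's empirical correlations or haplotype-count averages (those
data are not public). The empirical claims covered by tests are
sign/shape properties: negative correlation between triplet span and
$|\delta_{TMK}|$, and fewer segregating haplotypes for linked than for
unlinked triplets.

With `switch_prob = 0` every sample gamete is an exact founder copy, so
no triplet can exceed the pool depth in distinct haplotypes — the tests
use this as a truth-tracking oracle. With switching enabled,
recombination creates new haplotype combinations and counts may exceed
the pool depth; that is biology, not a bug.

## Known limitations

* **Boundary bias of the estimator mean.** When the generating value lies
  on the boundary of the parameter space ($\delta_{TMK} = 1/8$), every
  admissible estimate is $\le 1/8$, so the estimator mean is strictly
  below the truth by $O(1/N)$ (about $6\times10^{-4}$ at N = 306). This
  is a property of *any* valid estimator — a phase-known gamete-counting
  oracle shows the same bias as the EM — and the acceptance test that
  expects the mean within 3 Monte-Carlo SE of the boundary value is left
  failing by design. RMSE still decreases monotonically with N.
* Loci with more than two alleles, and systems of more than three loci,
  are out of scope (the E-step enumeration would extend, but nothing else
  is built for it).
* The deterministic recursion has no drift; the drift simulator has no
  mutation.
* LRT p-values rely on an asymptotic chi-square(4) that is only nominal
  near parameter-space boundaries.
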