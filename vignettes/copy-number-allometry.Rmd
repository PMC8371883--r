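---
title: "Ribosomal gene allometry and copy-number bias correction"
author: "rrnallometry"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ribosomal gene allometry and copy-number bias correction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rrnallometry)
```

## The problem

SSU rRNA gene surveys (16S/18S amplicons, or marker-gene tallies from
metagenomes) count *gene copies*, not cells. The number of ribosomal
gene copies a cell carries, $R_c$, is the product of two highly
variable quantities: the number of ribosomal operons per genome, $R_g$
(roughly 1–15 in prokaryotes, far more in some eukaryotes), and the
ploidy level $P$ (genome copies per cell, which ranges from 1 to
hundreds; oligo- and polyploidy are common across bacteria, archaea and
unicellular eukaryotes). Correcting read counts for $R_g$ alone — the
rrnDB-style approach — still only yields genome-copy abundances, and
ploidy determinations are too scarce to correct for $P$ taxon by taxon.

The way out is allometric. Across microbes spanning about nine orders
of magnitude in cell volume, $R_c$ follows a power law of volume,

$$R_c = a\,V_c^{\,b}, \qquad a = 9.58,\; b = 0.66 \approx 2/3,$$

with $V_c$ in $\mu m^3$. Equivalently, in terms of the
spherical-equivalent diameter $D_c^0 = 2\sqrt[3]{3V_c/4\pi}$,

$$R_c = a\,(\pi/6)^b\,(D_c^0)^{3b} \approx 6.25\,(D_c^0)^{1.98},$$

i.e. ribosomal gene content scales essentially with cell *surface
area*. Because the law subsumes both $R_g$ and $P$, a single
morphological datum — cell volume, or even a rough size class — is all
that is needed to translate gene frequencies into cell-number or
biovolume community structure. That is what this package implements,
together with the fitting machinery used to establish such laws and
synthetic generators to validate the whole pipeline.

## Power-law fitting

`fitPowerLaw()` (and its trait-table wrapper `fitTraits()`) fits
$y = a x^b$ as an ordinary least-squares regression of $\ln y$ on
$\ln x$ — the standard treatment for traits spanning decades, where
multiplicative lognormal error is the natural noise model. Choices
worth stating:

* **Natural logarithms throughout.** Base-10 axes are presentation
  only; the estimates are invariant to the choice.
* **Plain OLS.** No weighting and no errors-in-variables (e.g. reduced
  major axis) correction: the predictor is treated as known, and the
  quantities reported downstream (exponent SE, $R^2$, slope t tests)
  are the classical OLS ones.
* **Back-transformed constant.** $a = e^{\hat\alpha}$ with the
  delta-method standard error $se(a) = a \cdot se(\hat\alpha)$. This is
  a symmetric first-order approximation to an asymmetric sampling
  distribution; for the uncertainty levels involved here it is
  adequate, and it is what we report.
* **Sufficient statistics retained.** Each `PowerLawFit` keeps its
  residual sum of squares and the centered sum of squares of $\ln x$,
  so `compareSlopes()` can run the classical pooled-variance two-slope
  t test,
  $t = (b_1 - b_2)\big/\sqrt{s^2(1/SSX_1 + 1/SSX_2)}$ with
  $s^2 = (RSS_1 + RSS_2)/(n_1+n_2-4)$, on $n_1+n_2-4$ degrees of
  freedom. This is the standard biometry procedure for independent
  regressions; it is cross-checked in the test suite both against an
  exact-arithmetic normal-equations oracle and against the
  interaction-term parameterization of a pooled `lm()`.

Degenerate inputs fail loudly: non-positive values (logs undefined),
fewer than three pairs, or zero variance in $\ln x$.

`filterTraits()` packages the dataset restrictions that matter when
re-fitting scaling laws: dropping records with $R_c \le 2$ (a floor
effect — copies per cell cannot fall below 1, which could flatten the
low end), dropping eukaryotes below 20 $\mu m^3$ (pico-eukaryotes,
whose organellar rDNA may inflate apparent cellular counts), and
domain-restricted subsets (with `"prokaryote"` meaning bacteria plus
archaea).

## Trait tables

`loadTraitTable()` reads the canonical per-taxon schema (`taxon_id`,
`domain`, `shape`, `dim1..dim3`, `volume_um3`, `rrn_per_genome`,
`ploidy`, `rrn_per_cell`, `genome_mbp`, `dna_per_cell_mbp`) and applies
the derivations used when such tables are compiled from the literature:

* range-valued cells (`"lo-hi"`, hyphen or en-dash) collapse to their
  **arithmetic mean** — the convention for averaging reported ranges;
  the geometric mean is deliberately not used. When both ploidy and
  operon number are ranges, each is averaged first and the averages
  multiplied (mean-then-multiply; the alternative orderings differ only
  at second order in the range widths);
* volumes missing but shapes present are computed from the standard
  idealizations (`shapeVolume()`): sphere $(\pi/6)d^3$, cylinder
  $(\pi/4)d^2l$, capsule (cylinder plus hemispherical caps — the
  conventional model for rods, included beyond the bare
  sphere/cylinder pair), and composites as sums of parts;
* $P$ missing but DNA content and genome size present:
  $P = \mathrm{DNA}/G$ (`derivePloidy()`), both in Mbp-equivalents
  (masses convert at 1 pg = 978 Mbp, `fgToMbp()`);
* $R_c$ missing but $P$ and $R_g$ present: $R_c = P R_g$
  (`deriveRc()`).

Nothing else is imputed. A record with only one of $\{P, R_g\}$ keeps
its missing $R_c$ and is silently absent from fits that need it
(`completeCases()`); incomplete cases are data, not errors.
Inconsistencies are errors: $R_c$ disagreeing with $P R_g$ by more than
1% (a tolerance that accommodates range-averaged inputs), DNA per cell
below the size of one genome copy, non-positive volumes.

## The correction

Given per-taxon frequencies $F_r(i)$ and volumes $V_c(i)$, with
$R_c(i)$ from the model:

$$F_c(i) = \frac{F_r(i)/R_c(i)}{\sum_j F_r(j)/R_c(j)}, \qquad
  F_v(i) = \frac{F_c(i)\,V_c(i)}{\sum_j F_c(j)\,V_c(j)}.$$

With a sample-level qPCR total $R_s$ (copies per unit mass, volume or
surface): $R(i) = F_r(i)R_s$, $C(i) = R(i)/R_c(i)$ cells and
$V(i) = C(i)V_c(i)$ biovolume per sample unit, with
$\sum_i R(i) = R_s$ by construction. Biovolume doubles as a biomass
proxy under near-constant cell density (~1.008 g/ml). The direction of
the bias is fixed by $b > 0$: at equal read frequencies the
larger-celled taxon always has the smaller cell fraction and the larger
biovolume fraction — raw ribosomal tallies overestimate large microbes
in cell terms (bias growing with the square of linear size) and
underestimate them in biomass terms (bias growing with $V_c^{2/3}$).

Implementation conventions:

* frequencies are interpreted proportionally; inputs that do not sum
  to 1 (read counts, percentages) are renormalized with a warning;
* zero-frequency taxa are carried through with $F_c = F_v = 0$ rather
  than dropped, so outputs align row-for-row with inputs;
* the default model constants are the printed `(9.58, 0.66)`; the
  idealized exponent 2/3 is one flag away
  (`allometricModel(idealized = TRUE)`), since fitted and idealized
  forms are both in circulation.

## Size bins

When only rough sizes are known, taxa can be assigned to the 13
diameter classes 0.2–0.3, 0.3–0.4, 0.4–0.6, 0.6–0.9, 0.9–1.2, 1.2–1.5,
1.5–2.1, 2.1–2.9, 2.9–4.1, 4.1–5.8, 5.8–8.2, 8.2–11.6, 11.6–16.4 µm.
A bin's representative volume and $R_c$ are the means of the values at
its two diameter edges. The within-bin variation statistic reported by
`binTable()` needed a concrete definition (none is standard): we use
the relative deviation of the model prediction at the bin's mean edge
volume from the mean of the edge predictions,
$100\,|R_c(\bar V) - \bar R_c|/\bar R_c$. Under this metric every bin
of the default scheme stays below 8% (the maximum is ~3.7%), smaller
than the ~13% relative SE of the law's normalization constant — which
is what makes binning an acceptable surrogate for exact volumes.
Intervals are half-open $[lo, hi)$ with the top edge closed (the
boundary convention is otherwise arbitrary; it is stated so it is
testable).

## Synthetic data

The generators define the conditions under which the pipeline is
validated:

* `simulateTraitTable()` draws volumes **log-uniformly** over
  $[10^{-2}, 10^{7}]\ \mu m^3$ — nine decades, mirroring the even
  coverage of log axes in empirical compilations — and scatters
  $R_c = a V_c^b e^\varepsilon$ lognormally. Defaults: $n = 107$ taxa,
  $a = 9.58$, $b = 2/3$, and $\sigma = 1.61$, derived analytically
  (`lnNoiseForR2()`) so the expected ln–ln $R^2$ is 0.86; at $n = 107$
  this same $\sigma$ yields an exponent SE of ≈ 0.03. Domain labels
  are assigned by a crude size threshold (eukaryote above
  100 $\mu m^3$), sufficient for exercising domain filters.
* `simulateCommunity()` runs the forward model: a community of known
  cell counts and volumes contributes copies
  $\propto count \cdot R_c(V_c)$, optionally resampled multinomially at
  a sequencing depth. Without resampling, `cellFractions()` inverts the
  forward map exactly (a round trip the tests verify to $10^{-9}$);
  with resampling, recovery is checked against delta-method multinomial
  standard errors.

What the generators deliberately do **not** emulate: phylogenetic
correlation among taxa, PCR/primer bias, chimeras, DNA-extraction
efficiency, compositional read-count noise beyond multinomial sampling,
or intraspecies variability of $P$ with growth stage. Passing tests
therefore demonstrate correctness of the estimators under the stated
statistical model, not robustness to every artifact of real surveys.

## Numerical choices and problem sizes

Fits go through `stats::lm()` on logs; fraction pipelines are closed
form. Tolerances in the test suite: $10^{-9}$ (relative) for algebraic
round trips, $10^{-12}$ for hand-arithmetic oracles, $3\sigma$ bounds
for stochastic recovery. The validation suite uses 107-point trait
tables (500 replicates for the exponent-recovery check, mean within
0.01 of truth), 1000 randomized profiles for conservation properties,
and depth $10^5$ for resampling checks; `scripts/acceptance.R`
recomputes the same battery at 300 replicates in a few seconds.

## Limitations

* The correction is only as good as the volumes fed to it, and the
  empirical law carries real scatter ($R^2 = 0.86$): per-taxon
  predictions of $R_c$ have roughly a factor-$e^{1.6}$ spread, which
  averages out over communities but limits single-taxon precision.
* Totals anchored to qPCR inherit qPCR's own extraction and
  amplification biases; the package propagates, but cannot remove,
  them.
* Cross-sample comparisons of raw $R_s$ are not meaningful when size
  spectra differ between samples; compare cells or biovolume after
  correction instead.
* The 107-case literature compilation behind the default constants is
  a journal supplement and is not redistributed here; `fitTraits()`
  plus `filterTraits()` reproduce its published analyses when a
  transcription is supplied (see the test suite), and the package
  defaults simply encode the published constants.
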