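---
title: "Combined family- and population-based association testing: model and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Combined family- and population-based association testing: model and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(popfam)
```

## The problem

Genetic studies of inherited disease often accumulate *mixed* data: affected
offspring with genotyped parents (case-parent trios) alongside unrelated
healthy controls. The two halves carry different, partly overlapping evidence
about a candidate SNP. A case-control comparison is sensitive to allele
frequency differences but ignores which parental alleles were transmitted; a
transmission disequilibrium test (TDT) uses only the segregation signal from
heterozygous parents and ignores the controls entirely. Analyzing the halves
separately wastes power and leaves the overall evidence hard to summarize;
naively adding the two statistics ignores that they are correlated, because
the trio offspring are the cases of the case-control half.

`popfam` implements POPFAM, a nonparametric combined test for exactly this
design, together with the conditional genotype simulator and the
type-I-error / power machinery used to validate it.

## The statistics

At a biallelic marker coded as counts of the minor ("1") allele, with
$N$ trios, $M$ controls, case genotypes $R_j$, control genotypes $S_k$,
$H$ heterozygous parents overall and $T = \sum T_i$ minor alleles transmitted
from heterozygous parents to their affected offspring:

**Population component (trend test).**
$$P = \frac{\bar R - \bar S}{\sqrt{\sigma^2 (1/N + 1/M)}},$$
where $\sigma^2$ is the variance of a per-person allele count. Under HWE,
$\sigma^2 = 2\hat p(1-\hat p)$ with $\hat p$ the pooled (cases + controls)
minor allele frequency, and $P$ then coincides with the classical two-sample
z-test of allele proportions. Without HWE, a method-of-moments estimator
$\hat\sigma^2 = [4g_2 + g_1 - (N+M)\bar g^2]/(N+M)$ is available
(`variance = "mom"`), where $g_1, g_2$ count pooled individuals with one and
two minor alleles. Both modes pool cases and controls, which keeps the two
variance options mutually consistent.

**Family component (Wald test of Mendelian segregation).**
$$F = \frac{T - H/2}{\sqrt{H/4}} = 2\sqrt{H}\left(\frac{T}{H}-\frac12\right),$$
which squares to the classical TDT chi-square $(b-c)^2/(b+c)$ with
$b = T$, $c = H - T$. The package exposes a general null transmission
probability `p0` (default 1/2) as plumbing for designs where the reference
transmission rate is not one half; only `p0 = 1/2` is exercised by the
simulation study.

**Null covariance.** Both components are standardized, but they are
positively correlated under the null because the trio offspring appear in
both. Conditional on the parental genotypes, each case genotype is the
deterministic contribution of its homozygous parents plus the Bernoulli(1/2)
transmissions from its heterozygous parents, so
$\mathrm{Cov}(\sum R_j, \sum T_i) = H/4$, and after standardization
$$\tau = \frac{\sqrt H}{2N\sqrt{\sigma^2(1/N+1/M)}} \in [0, 1].$$
A useful check falls out algebraically: with $N = M$ and $H$ at its HWE null
expectation $2N\sigma^2$, $\tau = 1/2$ exactly. Because this expression was
derived here rather than taken from a published closed form, the test suite
gates it against an independent Monte-Carlo oracle: at five $(N, M, p)$
settings, the mean per-replicate $\tau$ must match the empirical correlation
of $(P, F)$ over $10^5$ null replicates within three Monte-Carlo standard
errors.

**The combined statistic.**
$$Z = \frac{wP + (1-w)F}{\sqrt{w^2 + (1-w)^2 + 2w(1-w)\tau}},$$
asymptotically $N(0,1)$ under no association; p-values are two-sided
throughout (the testing problem has no privileged direction, and
two-sidedness makes the minor-allele coding choice irrelevant).

**The weight.** The power-optimal $w$ depends on the unknown relative power
of the components. Two practical choices are exposed: `weight = "half"`
(the default, $w = 1/2$ — appropriate when the components have comparable
power, e.g. with equal numbers of cases and controls, and the setting used
throughout the simulation study) and `weight = "sample_size"`, which sets
$w = A/(A+H)$ with $A = NM/(N+M)$, half the harmonic mean of the case and
control counts, so the family side gains weight as informative parents
accumulate. A fixed numeric `w` is also accepted.

## Degenerate and messy inputs

* $H = 0$ (no heterozygous parents): $F$ carries no information; the test
  returns $Z = P$ with $w = 1$, $\tau = 0$, flagged `H0_fallback`, rather
  than failing.
* Marker monomorphic in the pooled sample: $P$ is undefined
  ($\sigma^2 = 0$); the test returns $Z = F$ when $H \ge 1$, flagged
  `monomorphic`, and errors only when neither component exists. In a
  multi-marker scan (`assoc_scan()`) such markers become flagged rows and
  never abort the scan.
* Mendelian-inconsistent trios (a child genotype impossible given the
  parents) are dropped with a warning by default; `inconsistent = "error"`
  aborts instead. The transmission count $t$ is determined without phasing:
  $t = \text{child} - \#\{\text{parents with genotype } 2\}$, valid iff
  $0 \le t \le h$.
* Missing genotypes: a trio missing any member drops out of $F$; its child
  still contributes to $P$ when genotyped. Controls with missing genotypes
  are dropped per marker.

## The simulator

`simulate_alt_data()` draws data *conditional on affection status* under a
two-locus model: a disease locus with risk allele frequency `daf` and
penetrances $(f_0, f_1, f_2)$, observed through a marker in LD with it.
Haplotype frequencies come from the margins and $D' \in [0,1]$ via
$D = D' \cdot D_{max}$, $D_{max} = \min(p_m(1-p_d), (1-p_m)p_d)$, with the
marker minor allele coupled *positively* to the risk allele — the sign is
irrelevant to a two-sided test, and positive coupling is the configuration
in which the marker tags the risk allele. Parents are random-mating draws of
two haplotypes each; each parent transmits one haplotype uniformly at
random; the trio is accepted with probability equal to the offspring's
penetrance (so the acceptance rate is the population prevalence, about 5%
under the default scenarios, and rejection sampling is cheap). Controls are
accepted with probability one minus their penetrance by default
("healthy controls"); `controls_mode = "population"` disables that
conditioning — at a 5% prevalence the difference is small but not zero.
Correctness is tested against exact enumeration: the conditional
distribution of accepted-trio genotype triples is computable by summing over
all ordered parental-haplotype configurations and transmission choices, and
the sampler must match it cell by cell.

The default study conditions (the `popfam_scenarios()` table) are six
scenarios with `daf` = marker MAF from 0.03 to 0.30, $D' = 0.8$, phenocopy
rate $f_0 = 0.045$, and heterozygote/homozygote penetrances tuned so every
scenario implies a 5% population prevalence in closed form
($K = f_0(1-p)^2 + 2f_1 p(1-p) + f_2 p^2$); the scenarios are deliberately
neither additive, dominant, multiplicative nor recessive.

`simulate_null_data()` needs no disease locus at all: parents and controls
are HWE draws and offspring follow by fair transmission.

## The power study

`run_type1()` and `run_power()` run 200 trios + 200 controls per replicate,
1000 replicates per scenario, $w = 1/2$, HWE variance, two-sided
$\alpha \in \{0.05, 0.01\}$, and tabulate rejection proportions with their
binomial Monte-Carlo standard errors for the combined test and for the
standalone $P$ and $F$ referred to $N(0,1)$ ($F$ skips replicates with
$H = 0$; at these sizes and MAFs that never happens in practice). Replicate
$r$ of scenario $i$ uses seed `base_seed + (i-1) * n_reps + r`, so results
are reproducible and independent of execution order. The null simulations
default to MAF 0.2; nominal size is insensitive to the choice at these
sample sizes, and any MAF can be passed explicitly.

Problem sizes used by the shipped checks were chosen to estimate each
quantity to well under its decision tolerance: $10^4$ null replicates bound
the size estimate's SE at about 0.2 percentage points; 1000 replicates per
power cell (matching the reference conditions) give SEs of 1–1.6 points;
the $\tau$ oracle uses $10^5$ replicates per setting at 30–120 trios and
controls, where the correlation estimate's SE is about 0.003.

## Numerical and design notes

* The combined denominator $w^2+(1-w)^2+2w(1-w)\tau$ is positive for all
  $\tau \ge 0$ and $w \in [0,1]$; a non-positive value (possible only with
  a user-supplied negative $\tau$) raises an error rather than a NaN.
* `compute_tau()` validates $\tau \in [0,1]$ and rejects inputs that imply
  otherwise (e.g. an $H$ inconsistent with the marker variance), since that
  signals upstream corruption rather than a continuable state.
* Minor-allele coding in PED input is per marker, the rarer allele in the
  pooled sample, ties broken by allele-code order; the choice only flips
  signs and leaves two-sided p-values unchanged.
* The per-replicate loop in the study functions re-runs the full
  user-facing test; the vectorized `simulate_null_stats()` path exists for
  the large calibration checks and applies the identical exported formulas,
  so the two routes cannot drift apart silently.

## What passing simulations do and do not show

The simulator draws a single biallelic marker from a homogeneous
random-mating population with fully typed, error-free genotypes. Passing
calibration and power checks therefore says nothing about population
stratification (a stratification-robust population component is deliberately
out of scope), genotyping error, relatedness beyond the trio, multi-marker
LD structure, or extended pedigrees — large families are handled only by
decomposition into trios when both parents are genotyped. Asymptotic
normality of the components also degrades at very rare markers; the null
distribution checks are gated at MAF $\ge$ 0.09, and smaller MAFs should be
treated with care at these sample sizes.
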