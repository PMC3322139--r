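---
title: "Prior-informed FDR control for GWAS: methods and simulation design"
author: "priorfdr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Prior-informed FDR control for GWAS: methods and simulation design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(priorfdr)
```

## The problem

A genome-wide association scan tests hundreds of thousands of SNPs at
once, of which only a handful are truly associated. At such small
signal fractions, plain Benjamini–Hochberg (BH) FDR control buys little
power over family-wise control, but prior biological knowledge —
previously reported genes, linkage peaks — can be folded into the
multiple-testing step. This package implements and compares the three
standard ways of doing that:

* **WGA** (whole-genome adjustment): BH step-up at level $q$ applied
  once to all $m$ p-values. Rejects the $k$ smallest p-values, where
  $k = \max\{i : p_{(i)} \le i\,q/m\}$.
* **WEI** (weighted FDR control): each p-value is divided by a positive
  weight, $\tilde p_i = p_i / w_i$, and BH is applied to the
  $\tilde p_i$. FDR control at level $q$ is preserved provided the
  weights average to one, $\tfrac1m\sum_i w_i = 1$. In the *binary*
  scheme an indicator $U_i \in \{0,1\}$ marks SNPs in regions supported
  by prior information, and the two weight levels with ratio
  $r = w_1/w_0$ under the mean-one constraint are
  $w_1 = r\,m/(r\,m_1 + m_0)$ and $w_0 = m/(r\,m_1 + m_0)$, with $m_1$
  prioritized and $m_0 = m - m_1$ remaining SNPs. At $r = 1$ (or a
  degenerate allocation) all weights are 1 and WEI *is* WGA.
* **PSA** (prioritized subset analysis): BH is applied separately, at
  the same nominal $q$, to the prioritized subset and to the
  non-prioritized subset; the rejection set is the union. PSA needs no
  ratio parameter, but — because each subset is controlled on its own —
  the *overall* FDR of the pooled rejections carries no guarantee.

Bonferroni and Holm FWER procedures are included for reference. All
procedures use inclusive boundary comparisons and give tied p-values a
common fate; weighted p-values above 1 are kept unclamped (they are
never rejectable, so clamping would change no decision while making
$\tilde p = p/w$ inexact).

The interesting phenomenology, which the evaluation harness reproduces,
is: with informative priors PSA is the most powerful, followed by WEI
with larger $r$; with uninformative priors the power cost of either is
small; but PSA's overall FDR is slightly *inflated* when the
prioritized regions contain no true loci, because the prioritized
subset then contributes occasional pure-false-positive batches while
contributing no true rejections to the denominator. Lowering the
per-subset level to 4.4% restores overall control at 5%.

## Turning prior knowledge into subsets and weights

`allocate_snps()` marks a SNP prioritized when it lies within
`flank_bp` of a region boundary on the same chromosome; overlapping
regions do not double-count, so the allocation is idempotent and
order-invariant. A gene table with a 1 Mb flank gives the usual "SNPs
within 1 Mb of a previously reported gene" rule (a 2 Mb-plus-gene
span). Region files may be BED (0-based half-open, converted on read)
or a 1-based inclusive gene table; chromosome labels are matched as
opaque strings.

For simulation studies, `build_scenario()` constructs prioritized
region sets along three axes: the number of regions (6, 14, 22), the
region size (2 Mb, 20 Mb), and which of the six causal loci are
covered — eight accuracy scenarios from (i) none to (viii) all, encoded
once in `prioritization_scenarios()`. Covered loci get a region
centered on the locus (centering is an assumption; offsets are not
modelled). The remaining regions are *decoys* placed uniformly at
random on the marker map, non-overlapping, with centers kept at least
the region size plus a 2 Mb buffer away from every causal locus, so a
decoy can never harbour a SNP that counts as a true rejection. Decoy
placement is seeded and deterministic; placement failure raises an
error after bounded retries rather than silently relaxing the buffer.

## The genotype-level simulator

`haplotype_model()`/`draw_genotypes()` generate case-control panels
without any external reference data. Haplotypes are drawn per LD block
from a latent AR(1) Gaussian with parameter $\rho$ (default 0.8, block
size 50 SNPs, blocks never crossing chromosomes) and thresholded at the
allele-frequency quantile; a genotype is the sum of two independent
haplotypes. This latent-Gaussian block copula reproduces the feature
that matters for multiple testing — clusters of correlated significant
SNPs around a causal locus — while keeping marginal allele frequencies
exact and Hardy–Weinberg equilibrium guaranteed by construction. It
does *not* reproduce empirical human LD maps: no hotspots, no
inter-block decay, no population structure. Conclusions about method
*rankings* transfer; absolute power numbers do not.

The disease model is multiplicative in the risk-allele counts
$x_j \in \{0,1,2\}$ at six causal loci:
$\Pr(\text{affected} \mid x) = p_0 \prod_j \mathrm{GRR}_j^{\,x_j}$,
with minor alleles as risk alleles. The default configuration uses
three small-effect loci (GRR 1.34, MAFs 0.25/0.36/0.33) and three
large-effect loci (GRR 1.57, MAFs 0.43/0.31/0.30) and 5% prevalence.
Under HWE and inter-locus independence,
$E[\mathrm{GRR}^X] = ((1-f) + f\,\mathrm{GRR})^2$ for
$X \sim \mathrm{Bin}(2, f)$, so `calibrate_baseline()` sets
$p_0 = \text{prevalence} / \prod_j ((1-f_j) + f_j\,\mathrm{GRR}_j)^2$
in closed form; the test suite verifies prevalence recovery by
simulation. A relative-risk (identity-link) penetrance was chosen over
a logistic link because the effects are specified as genotypic
*relative risks*; the link is isolated in `disease_prob()` and
`p_base` is an explicit argument, so a different link can be swapped in.
Case-control sampling is plain rejection sampling to exact quotas
(default 500/500), with a progress guard for pathologically small
prevalence. QC mirrors common practice: SNPs failing the
Hardy–Weinberg exact test (standard conditional enumeration, plain
rather than mid-p) in *controls* at p < 1e-4 are excluded; the 1e-4
default is conventional and configurable. Association tests are the
1-df allelic $\chi^2$ on the 2×2 allele table and the 2-df genotypic
$\chi^2$ on the 2×3 genotype table (empty genotype columns collapsed,
df reduced accordingly), both without continuity correction.

## The statistic-level simulator and the scaled genome

Monte-Carlo FDR studies need thousands of genome-scale replicates, far
beyond what genotype-level simulation affords on a desk. The
statistic-level generator (`stat_panel_config()`,
`simulate_stat_panel()`) therefore draws per-SNP z-scores directly:

* marker map: 22 pseudo-chromosomes × 1,428 SNPs = 31,416 tests at
  8,900 bp spacing (~112 SNPs/Mb) — a one-tenth scale model of a 314k
  SNP genome-wide panel that keeps the SNP density, and hence the
  meaning of Mb-sized windows and regions, realistic;
* null SNPs: latent AR(1) Gaussian z-scores within 50-SNP blocks,
  $\rho = 0.8$; p-values are two-sided normal tails;
* causal loci: one lead $z \sim N(\mu, 1)$ per locus, with
  $\mu = 5.2$ for the small-effect and $\mu = 6.0$ for the large-effect
  loci, plus nine tag SNPs whose correlation with the lead decays as
  $0.8^{d}$ with SNP offset $d$. The decay mirrors the AR(1) null
  blocks and makes a detected locus show several (typically 2–4)
  significant SNPs rather than the whole cluster, which is the regime
  in which the PSA pooled-FDR inflation operates. The noncentralities
  put large-effect locus detection in the >0.95 range and small-effect
  detection near 0.86 at genome-wide BH, i.e. moderate-to-high power
  with ~19 rejections per replicate.

Replicates are indexed streams from one master seed (a fixed integer
mix of seed and replicate index, kept below $2^{31}$), so any replicate
is reproducible in isolation and method comparisons can share panels.

## The evaluation harness

`run_scenario_study()` runs, per replicate: panel simulation → every
requested method under every prioritization scenario → realized false
discovery proportion and per-locus detection flags. All methods and
scenarios see identical panels (paired replicates), which removes
between-panel noise from method contrasts; the study object keeps the
per-replicate matrices so paired standard errors can be formed. The
truth rule counts a rejected SNP as *true* when it lies within 1 Mb of
a causal locus on the same chromosome — the same window used for
locus-level power ("at least one significant SNP within 1 Mb") — and
uses the $0/0 \to 0$ convention for $V/R$. Both the window and the
convention are configurable/documented because SNPs in LD with a
causal locus have no observable null status.

The default study sizes are 2,000 replicates of the 31,416-SNP panel
for the FDR/power comparisons (the shared study behind the acceptance
tests and `scripts/acceptance.R`), and smaller maps for unit-level
properties. A full study takes on the order of a minute or two on one
CPU.

`permutation_fdr_estimate()` implements the empirical-FDR companion
used when analysing a real scan with PSA: permute phenotypes $B$
times, recompute the test, count null p-values at or below the largest
declared-signal p-value, divide by $B$ and by the number of declared
signals.

## What passing the harness does and does not show

Within the scaled study conditions the harness computes (and the test
suite asserts): WGA and WEI (r = 2, 5, 10) realized FDR at or below
the nominal 5% within Monte-Carlo error; PSA pooled FDR above 5% under
uninformative prioritization and back under control at a 4.4%
per-subset level; and the power ordering
PSA ≥ WEI(10) ≥ WEI(5) ≥ WEI(2) ≥ WGA under informative
prioritization, with near-negligible losses for PSA and small-$r$ WEI
when the prior is uninformative.

Two desk-scale distortions are worth stating plainly, because they are
properties of the scaling, not of the methods:

* the 1 Mb truth windows around six loci absorb ~4.3% of a 280 Mb
  scaled genome (vs ~0.4% at full scale), which lowers the attainable
  null mass and with it every realized-FDR mean by a few tenths of a
  percentage point; the PSA inflation consequently measures ~5.0–5.1%
  here rather than the ~5.6% seen at full scale, though its mechanism
  (decoy-subset false-positive batches against a ~19-rejection
  denominator) is exactly reproduced;
* the prioritized fraction $m_1/m$ is ~4.3% rather than ~0.4%, so the
  non-prioritized down-weight $w_0$ at $r = 10$ is ~0.72 rather than
  ~0.96, and the WEI(r = 10) power loss under an uninformative prior
  measures ~2.2 percentage points at the small-effect loci — above the
  ~2-point bound that holds at full scale. PSA and WEI at r ≤ 5 stay
  within it.

## Numerical and degenerate-input choices

* BH threshold comparisons are inclusive; ties share one fate (any
  rejected value's duplicates are rejected too).
* Weight vectors must satisfy mean one to a relative 1e-9;
  renormalization happens only on an explicit `renormalize = TRUE`,
  never silently.
* Empty PSA subsets are legal and degenerate to single-subset BH; an
  empty p-value vector is an error ("no tests"), as are p-values
  outside [0, 1].
* Monomorphic SNPs give p = 1 with a warning in the association tests
  and p = 1 in the HWE exact test; probability ties in the HWE
  enumeration are included using a 1e-12 relative tolerance.
* Decoy placement retries are bounded (default 1,000 per region) and
  failure is an error.
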