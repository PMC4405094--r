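---
title: "Genome partitioning of trait variation: models, simulator and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Genome partitioning of trait variation: models, simulator and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`wildarch` asks where in the genome the heritable variation of a
quantitative trait sits, using the data a long-term wild-population study
typically has: a dense biallelic SNP panel on thousands of individuals, a
SNP-derived pedigree, repeated phenotype measures, and annual census and
reproduction records. This vignette explains the statistical machinery, the
synthetic-data generator behind the test suite, and the design choices made
where the methods literature leaves options open.

## The animal models

All variance partitioning runs through one engine, `greml()`, an
average-information (AI) REML fitter for

$$ y = X\beta + \textstyle\sum_k Z_k u_k + e, \qquad
   u_k \sim N(0, \sigma^2_k K_k), \quad e \sim N(0, \sigma^2_e I), $$

where each $K_k$ is either a genomic relatedness matrix (GRM) over
individuals or the identity over the levels of a grouping factor. Fixed
effects are sex and age-at-measurement as multilevel factors; aliased
columns are dropped with a message. The non-genetic random terms are birth
year always, plus year of measurement and a permanent-environment
(identity-on-individual) term whenever measures are repeated; maternal
effects are deliberately not fitted. Partitioning then compares three
nested specifications: the whole-genome model (one all-autosome GRM), the
unit + complement model (a GRM from the SNPs of one chromosome or window
plus the complementary GRM), and the complement-only model. The unit's
contribution is tested by LRT with a $\chi^2_1$ reference.

**GRM estimator.** Off the diagonal,
$A_{jk} = \frac1m \sum_i (x_{ij}-2p_i)(x_{ik}-2p_i) / (2p_i(1-p_i))$; on
the diagonal the matching estimator
$A_{jj} = 1 + \frac1m\sum_i (x_{ij}^2-(1+2p_i)x_{ij}+2p_i^2)/(2p_i(1-p_i))$.
Allele frequencies default to the *full genotyped sample*, not the
phenotyped subset, and may be supplied externally; the source is recorded
on the object. With shared frequencies the estimator is exactly linear in
SNP sets ($m_{tot}A_{tot} = m_{sub}A_{sub} + m_{comp}A_{comp}$), which the
scan code exploits to derive every complement GRM by subtraction instead of
recomputation; a unit test asserts the identity to numerical precision.
Missing dosages are mean-imputed to $2p_i$ at GRM construction, so the
variance-component stages never see missing data. A reliability-shrinkage
option (`adjust_grm(mode = "reliability")`) scales off-diagonals by
$v/(v + c/m)$ against marker sampling noise; the exact transformation used
by common GRM software is undocumented, so this stand-in is provided but
defaults to off — with the SNP counts involved here the adjusted and
unadjusted fits differ very little.

**Numerics.** AI updates with step-halving; an EM step is substituted when
the AI system is singular or every halved step fails. Components are floored
at $10^{-8}\,\mathrm{var}(y)$ and treated as boundary estimates (their SEs
are reported as `NA`). Starting values split $\mathrm{var}(y)$ equally
across components; on non-convergence the fit restarts once from perturbed
values. Convergence requires a relative log-likelihood change below
$10^{-8}$ *and* a score norm below $10^{-4}$, with a 200-iteration cap;
non-converged fits are flagged, and the scan functions count and report
them rather than dropping them silently. The reported REML log-likelihood
omits the additive $-(n-p)\log(2\pi)/2$ constant, which cancels in every
LRT. Marker-built GRMs are legitimately slightly indefinite (the GCTA-form
diagonal is not the Gram diagonal, and strongly so for 150-SNP windows);
the input check therefore rejects a structure only when its negative
spectrum is comparable in magnitude to its positive one.

**LRT reference.** Tests of a single variance component use the plain
$\chi^2_1$ upper tail, not the $\tfrac12(\chi^2_0+\chi^2_1)$ boundary
mixture — matching how such partitioning analyses conventionally report
them; the mixture is available via `mixture = TRUE`. The plain reference is
conservative, which the permutation test in the acceptance suite confirms
(empirical size below nominal).

**Window rule.** Regions hold 150 adjacent SNPs and start 75 apart within
each chromosome; trailing windows keep whatever SNPs remain and are
retained only with at least 113 SNPs. The window-level significance
threshold is $\alpha$ divided by *half* the number of converged windows,
because consecutive windows overlap by 50% and are not independent tests.
Chromosome-level tests are deliberately unadjusted.

## GRAMMAR association scan

Stage one fits the whole-genome animal model and extracts conditional
residuals $y - X\hat\beta - \sum_k Z_k\hat u_k$ — all BLUPs subtracted, not
only the fixed effects — averaged per individual over repeats. Stage two
score-tests each SNP: $\chi^2 = n r^2$ with $r$ the residual–dosage
correlation (missing dosages pairwise-excluded). Because the genomic BLUP
absorbs part of every true signal, the statistics are deflated
($\lambda < 1$); $\lambda$ is reported as a diagnostic and no genomic
control is applied, so the scan is conservative. Candidate SNPs are then
refitted inside the full mixed model as a minor-allele-dosage covariate
(minor allele defined in the full genotyped sample), giving the unbiased
additive effect $a$, its Wald test, and the decomposition
$V_{SNP} = 2pqa^2$, $h^2_{SNP} = V_{SNP}/V_P$, and $V_{SNP}/V_A$. Ties for
the top SNP break by smaller bp, then id.

## Selection analysis

Fitness measures follow the standard wild-population definitions: annual
survival (AS) past the end of each year of study membership, annual
recruits (AR; offspring born that year that survive their first year),
lifetime breeding success (LBS; all offspring, cohort-window restricted to
avoid censoring bias) and lifetime recruits (LR). Genotype relative fitness
$w$ is each class mean over the fittest class mean, $s = 1-w$, with
percentile bootstrap CIs resampling individuals within genotype class
(default 1000 draws, seed logged); classes with fewer than 5 individuals
are flagged rather than dropped. The heterozygote-advantage equilibrium
$q_{eq} = s_1/(s_1+s_2)$ is refused unless the heterozygote is the fittest
class, and its CI propagates the bootstrap draws of $(s_1, s_2)$. The full
Bayesian GLMM treatment of fitness (MCMC, Poisson/binomial links) is out of
scope here; the genotype-contrast machinery is simpler and is validated
only on synthetic data — it is not equivalent to those models.

**Gene-drop null.** Observed allele-frequency trends (OLS slope of yearly
frequency on year, at least 3 years) are compared with a drift null built
on the fixed pedigree: founders keep their observed genotypes (ungenotyped
founders draw from the founder frequency), descendants are re-sampled by
Mendelian transmission, and yearly frequencies are recomputed over exactly
the observed individual-year membership. The one-tailed P follows the sign
of the observed slope; both tails are reported. Which animals enter the
yearly series is configurable; the default is all genotyped animals alive
that year. Unbiasedness is tested against the exact pedigree recursion
$E[d_i] = (E[d_{dam}] + E[d_{sire}])/2$ rather than against the founder
frequency, because conditional on one pedigree the expected trajectory is
the founder-contribution-weighted frequency, not a constant.

## Haplotype sharing

A core haplotype is the allele string over six SNPs: three upstream, the
focal SNP itself, and two downstream (the "six SNPs" only add up if the
focal SNP is counted — this is deliberate and worth flagging). Cores
observed at least 5 times are retained; the retention threshold is
configurable since "fewer than 5" and "more than 5" conventions both
circulate. For each pair of core-carrying chromosomes (focal × reference
breed), alleles are compared outward from the core's edges, and the HS span
runs from the last matching SNP upstream to the last matching SNP
downstream. Measuring between last-matching SNPs (rather than to first
mismatches) makes an immediate double-sided mismatch yield exactly the core
span, so HS ≥ core span is an invariant; scans truncate at the window edge
(default ±5 Mb around the focal SNP). Pairs are always compared per
chromosome and never collapsed, even when cores differ only outside the
window. The implementation is vectorized over reference chromosomes and is
tested for exact equality against a plain per-pair scanning oracle on
random panels.

## The synthetic-data generator

`simulate_population()` produces the structure the analyses assume
*mechanistically*, not parametrically: LD comes from founder haplotypes
built as mosaics of a small ancestral pool (default 10 haplotypes, mosaic
switch rate `founder_generations × recomb_rate` = 0.5/Mb) and from
pedigree transmission with Poisson crossovers on a uniform 1 cM/Mb map, no
interference. Founder minor-allele frequencies are drawn per SNP from
`maf_range` and enforced by minimal allele flips. Mating is random within
year among surviving adults, sexes 50:50; one cohort is born per year, so
generations overlap as in the study system. QTLs are planted at a target
founder MAF on locally similar haplotype backgrounds (so flanking SNPs tag
them); their fitness modes multiply both survival and parental sampling
weights, which lets selection genuinely propagate through the pedigree.
Phenotypes sit on a unit phenotypic scale: the polygenic breeding value is
built from per-chromosome SNP-effect sums with variance proportional to
chromosome length and rescaled so its realized variance equals
`polygenic_h2` exactly; birth-year, year, permanent-environment and
residual deviations carry the remaining shares (they must sum to 1), and
planted-QTL variance rides on top. Default architecture parameters mirror
the motivating study system: major QTLs at MAF ≈ 0.05–0.10 explaining
~10–15% of $V_A$ (additive effects of 0.6–0.9 phenotypic SD per copy),
heritabilities of 0.25–0.55, ~2.8 measures per measured adult.

**Admixture.** When configured, immigrant individuals carrying haplotypes
from a separate donor ancestral pool enter `donor_generations` years before
the end at the configured proportion, and every SNP of every haplotype
carries a donor/native descent flag through transmission. A `donor_only`
QTL allele is placed solely on donor haplotypes, riding on a locally
homogenised donor background — emulating a variant introgressed on
essentially one haplotype. Because generations overlap, immigrants survive
into the sampled panel and donor tracts merge, measured donor-segment
lengths are systematically longer than the discrete-generation
$1/g$-Morgan expectation; the tests therefore assert the decay of tract
length with `donor_generations`, not the discrete-generation constant.

**What the simulator does not emulate.** Realistic demography
(overdispersed reproductive success, sex-biased dispersal), allele-spectrum
mismatch between genotyped SNPs and causal variants, genotyping error,
phasing error (all haplotypes are generated phased and error-free), and
any X-linked inheritance. Passing tests therefore validate the estimators
and their wiring under clean IBD structure, not robustness to those
real-data artefacts.

## Problem sizes used in the tests

The automated suites run desk-scale versions of the study design, chosen
once as realistic for the statistic each exercises: heritability recovery
uses 50 replicates of ~500 measured single-record individuals over two
chromosomes; QTL localisation uses 25 replicates of ~650 adults (~1100
repeated measures) on four 300-SNP chromosomes with the two-QTL leg-length
architecture; the length regression uses eight autosomes spanning 25–240 Mb
with SNP density proportional to length, where the length spread gives the
8-point regression adequate power; the gene-drop uniformity check uses 150
unlinked loci dropped through one pedigree; haplotype sharing uses a
donor proportion of 0.3 introduced 5 generations back, of the order of the
admixture fraction documented in the motivating system. The acceptance
script (`scripts/acceptance.R`) re-runs reduced versions of the same
computations from a single command-line seed.

## Known limitations

* The AI-REML engine is dense ($O(n^3)$ per iteration); it is comfortable
  to a few thousand observations, which covers study systems of this kind,
  but it is not an out-of-core GWAS-scale solver.
* Standard errors for variance ratios use the first-order delta method from
  the AI matrix and are unavailable for boundary estimates.
* The regional threshold convention (alpha over half the converged windows)
  and the plain $\chi^2_1$ reference are faithful to the partitioning
  literature rather than optimal; both are configurable.
* `selection_coefficients()` contrasts raw genotype means; covariate
  adjustment (maternal age, twin status) belongs to a GLMM layer that is
  intentionally out of scope.
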