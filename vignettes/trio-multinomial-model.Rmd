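---
title: "Multinomial modelling of child, maternal, imprinting and interaction relative risks from family genotype data"
author: "triomult"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multinomial modelling of family genotype data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(triomult)
```

## The scientific problem

Case/control association scans detect effects of an individual's own
genotype, but many conditions — especially pregnancy and early-life
outcomes — can instead be driven by the *mother's* genotype, by
*maternal–fetal genotype interactions*, or by *parent-of-origin
(imprinting)* effects, where the risk conveyed by an allele depends on
which parent transmitted it. None of these is identifiable from unrelated
cases and controls alone: they require genotypes of one or both parents of
each case, plus (optionally) control families.

`triomult` estimates these effects jointly by maximum likelihood from
whatever mixture of family units a study yields: complete case/parent
trios, case/mother and case/father duos, parental matings of a case or
control child, single genotyped parents, and singleton cases and
controls. It also implements the companion per-SNP *extraction* step that
reduces arbitrary nuclear pedigrees in PLINK text format to the most
informative such unit per family, and a seeded simulator of all unit
types used throughout the test suite.

## Penetrance model

Genotypes are risk-allele counts $g \in \{0, 1, 2\}$ (the risk allele is,
by default, the minor allele). For a child with genotype $g_c$ whose
mother and father carry $g_m$ and $g_f$, disease risk is modelled as a
baseline $\alpha$ times multiplicative factors:

* $R_1, R_2$ — child carries one / two risk alleles;
* $S_1, S_2$ — mother carries one / two risk alleles;
* $I_m, I_p$ — a heterozygous child's risk allele was maternally /
  paternally inherited;
* $\gamma_{ij}$ — mother carries $i$ and child $j$ copies
  (maternal–fetal interaction; $\gamma_{00} \equiv 1$ is the reference).

For example, a trio with $g_m = 2$, $g_f = 0$, $g_c = 1$ (where the
child's single risk allele is necessarily maternal) has penetrance
$\alpha R_1 S_2 I_m \gamma_{21}$; `penetrance_multiplier(2, 0, 1,
"maternal", rp)` returns the $\alpha$-free product. The baseline $\alpha$
is never a parameter: it cancels when conditioning on the child being
affected, which is also why only *relative* risks are estimable from this
design.

Two conventions are worth stating explicitly, because the literature is
ambiguous:

* **Imprinting factors apply to heterozygous children only.** A
  homozygous child inherited a risk allele from both parents; attaching
  $I_m I_p$ there would confound the product with $R_2$. In the one cell
  where the parental origin is genuinely ambiguous (het × het mating,
  het child), the two phased transmission paths are equally likely a
  priori, so the cell carries the phase average $(I_m + I_p)/2$.
* The interaction grid is indexed by (mother count, child count);
  $\gamma_{02}$ and $\gamma_{20}$ exist in the grid for completeness but
  touch no Mendelian-consistent configuration and are therefore not
  estimable (the package refuses to free them).

## The 15-cell multinomial and its collapses

Exactly 15 ordered (mother, father, child) genotype configurations are
consistent with Mendelian inheritance at a biallelic autosomal locus;
`trio_cells()` enumerates them in the frozen canonical order used by
every count vector and file in the package. The probability of observing
cell $i$ in a case trio is

$$ P(i \mid \text{child affected}) \;\propto\;
   \mu_{t(i)} \; c_i \; w_i \; \pi_i , $$

where $\mu_{t(i)}$ is the mating stratum of the parental pair, $c_i =
2^{\#\text{het parents}}$ counts the parental allele arrangements
carrying that genotype pair, $w_i = P(g_c \mid g_m, g_f)$ is the
Mendelian segregation weight, and $\pi_i$ is the penetrance multiplier
above (phase-averaged where needed). Control units use the same
expression with $\pi_i = 1$ — i.e. control genotype configurations follow
the general population, a rare-disease assumption when controls are truly
unaffected. The vector is normalised over the 15 cells
(`case_trio_cell_probs()`, `control_trio_cell_probs()`); the propriety of
this construction is verified in the tests against a brute-force oracle
that enumerates parental pairs and phased transmissions directly.

A unit with missing members cannot distinguish all 15 cells. Its
observable combinations are the partition of the cells induced by
marginalising over the unobserved members (`collapse_map()`): 15 for
trios, 9 for parental matings, 7 for duos, 3 for single parents and
singletons. The duo maps reproduce the published 7-row table (e.g. the
het-mother/het-child combination pools cells 5, 9 and 11); all other maps
are generated from the same marginalisation rule rather than hard-coded,
so the published table serves as a regression test. The log-likelihood of
a unit table is the multinomial likelihood of its collapsed probability
vector, and the total log-likelihood of one SNP is the sum over all unit
tables, case tables using the case vector and control tables the control
vector, with one shared set of stratification parameters
(`total_log_likelihood()`).

## Stratification assumptions and their nesting

The nuisance structure of the parental matings can be held at four levels
(`strat_params()`):

* **CPG** — conditional on parental genotypes: nine strata
  $\mu_1$–$\mu_9$, one per *ordered* parental pair; most robust, least
  powerful.
* **CEPG** (default) — mating symmetry: the six strata $\mu_1$–$\mu_6$
  of the unordered mating types.
* **PAE** — parental allelic exchangeability: CEPG with
  $\mu_4 = \mu_3$.
* **HWE** — Hardy–Weinberg equilibrium and random mating: all strata are
  functions of a single allele frequency $q$.

Because the strata multiply *per allele arrangement* (the factor $c_i$
above is a fixed cell coefficient), HWE induces
$\mu_t = q^{a_t}(1-q)^{4-a_t}$ with $a_t$ the parental risk-allele total
of the type (`hwe_mating_mu()`), which satisfies $\mu_4 = \mu_3$. This is
what makes the hierarchy nest cleanly: HWE ⊂ PAE ⊂ CEPG ⊂ CPG, so fitted
log-likelihoods are monotone along that order (asserted in the tests on
every simulated dataset). Had the multiplicity been folded into the
strata instead, CEPG and CPG fits would be unchanged (a within-type
reparameterisation) but HWE would imply $\mu_4 = 4\mu_3$ and the PAE
constraint would no longer contain it.

During fitting, the all-reference stratum ($\mu_6$, or $\mu_9$ under CPG)
is fixed at 1: the explicit normalisation over the 15 cells absorbs the
remaining scale, so CEPG contributes 5 free stratification parameters,
PAE 4, CPG 8, and HWE a single $q$. Under HWE, $q$ is *estimated*, with
the marker-file frequency as its starting value — the frequency seeds the
optimiser, it does not pin the parameter.

## Identifiability

The 15 cells provide 14 degrees of freedom, but the risk multipliers act
on cells only through a coarse pattern, and some directions coincide with
stratification directions. `max_estimable_risk_params()` quantifies this:
starting from the CEPG strata it greedily adds parameters from the menu
$\{R_1, R_2, S_1, S_2, \gamma_{11}, \gamma_{12}, \gamma_{21},
\gamma_{22}, I_m, I_p\}$, accepting an addition only if the Jacobian of
the 15-cell probability map (computed analytically at a seeded generic
interior point) gains a rank. Exactly **7** are accepted; the count is a
generic-rank (matroid) property, so the greedy order is irrelevant. The
numerical rank uses a singular-value threshold of $10^{-8}$ relative to
the largest singular value. Fitting more than 7 risk parameters jointly
is therefore refused information by the data, and model building should
proceed through nested tests.

Multiplicative constraints ($R_2 = R_1^2$, $S_2 = S_1^2$) and the PAE tie
$\mu_4 = \mu_3$ are applied by expansion of the free vector
(`apply_constraints()`), never by penalties.

## Estimation

`fit_model()` maximises the collapsed multinomial log-likelihood by BFGS
on log-transformed parameters ($q$ on the logit scale), so positivity
holds by construction and the optimisation is unconstrained. The gradient
is analytic: for every free parameter, the derivative of the log cell
mass is an exponent pattern over the 15 cells (θ-dependent only for
$I_m$/$I_p$ in the phase-averaged cell and for $q$), which makes a
gradient evaluation as cheap as a likelihood evaluation and keeps a
typical single-SNP fit in the low milliseconds. Convergence uses a
relative log-likelihood tolerance of $10^{-12}$ with at most 500
iterations; fits from perturbed starting points agree to ~$10^{-7}$ in
log-likelihood on regular data (tested). Stratification parameters start
at their random-mating shape at the marker frequency, risk parameters at
1. Points the parameterisation cannot represent (overflow during a long
line-search step) score a large negative value so the line search
backtracks rather than aborts.

Standard errors come from the inverse of the numerically differentiated
(central-difference) Hessian of the analytic gradient at the optimum,
delta-method-transformed to the natural scale; if the Hessian is not
positive definite the SEs degrade to `NA` rather than failing the fit.
Estimates that run to the edge of the representable range (beyond
$10^{\pm 3}$) raise a `boundary` flag; no boundary correction is
attempted, matching the plain chi-squared usage downstream.

`lrt()` forms $2\Delta\ell$ clipped at zero with degrees of freedom equal
to the difference in free-parameter counts, referred to the chi-squared
upper tail. Under null simulation the resulting p-values are uniform
(Kolmogorov–Smirnov check over 2000 replicates in the tests). No
multiple-testing adjustment is applied; `analyse_snps()` reports raw
p-values per SNP, skips degenerate SNPs with an explicit reason instead
of dropping them, and accepts a batch range whose concatenated results
are identical to a full run, for embarrassingly parallel scans.

## Extraction from pedigree files

`read_pedigrees()` parses PLINK text `.ped`/`.map` (phenotype 2 = case,
1 = control, 0/−9 = unknown; a half-called genotype is wholly missing).
Per SNP, `assign_risk_allele()` takes the minor allele by sample count as
the risk allele — an exact tie breaks to the lexicographically smaller
label, a documented local convention — unless overridden, and the allele
frequency is estimated from founders only (allele counting), because
transmitted genotypes are not independent draws; if no founder is
genotyped the estimate falls back to all individuals with a warning.

`extract_count_tables()` then selects, per family and per SNP, the
highest-preference unit constructible from non-missing genotypes, in the
fixed order: case/parent trio, case/mother duo, case/father duo, case,
case parental mating, case mother, case father, control parental mating,
control/mother duo, control/father duo, control. (There is no control
trio unit: a fully genotyped control family enters as a parental mating.)
The anchoring case is the stated proband or the first affected individual
in file order, individuals with parent links taking precedence so that an
affected child outranks an affected founder; control units are anchored
the same way. Extraction is genuinely per-SNP: a family contributes a
trio where complete and a duo where one parent's call is missing.
Mendelian-inconsistent trios and duos are discarded *at that SNP only*
and tallied in a machine-readable log. An option emits multiple trios
(or control matings) per pedigree; it can bias sibling-correlated designs
and is off by default.

Count tables are written one file per unit type, one row per SNP, columns
in the frozen combination order, with header comments naming the unit and
columns; `read_count_files(write_count_files(x)) = x` exactly.

## The simulator

`sim_design()`/`simulate_unit_tables()`/`simulate_ped_files()` generate
data under the exact model being fitted: for every family unit a complete
latent trio cell is drawn from the case (or control) 15-cell distribution
under HWE at frequency `q` — conditional-on-affection sampling, so no
baseline penetrance is needed — and the unit type determines which
members are emitted or tabulated. A rejection-sampling path with an
explicit baseline (`sample_case_trios_rejection()`) exists purely as an
independent cross-check of the conditional sampler and agrees with it in
distribution (tested). Both output routes consume the same latent draws,
so with equal seeds the extracted count tables equal the directly
simulated ones bit for bit; this round trip is the core end-to-end test
of the extraction module.

Default study conditions follow the published experimental designs: the
six-unit comparison design (50 each of case/parent trios, case/mother
duos, case/father duos, control matings, control/mother and control/father
duos) with effects such as $R_2 = 2$ or $S_2 = 2$; the genome-scan mix
(200 case/parent trios, 200 case/mother duos, 200 control/mother duos,
1000 controls) with $R_1 = 1.5, R_2 = 2.25$ or $S_1 = 2, S_2 = 3$; and
200-trio interaction designs with $\gamma_{01} = 2$ or $\gamma_{10} = 2$.
The allele frequency is not printed for the single-SNP experiments; 0.3
is used throughout — a common-variant frequency at which the minor allele
is unambiguous and all strata are populated — and recorded in each
design. Missing genotype calls are independent Bernoulli(`p`) per
individual per SNP.

What the simulator does *not* emulate: linkage disequilibrium between
SNPs (markers are independent; single-SNP likelihood validation does not
need LD), genotyping error (Mendelian inconsistencies arise only if
injected), population stratification or assortative mating (HWE
generation; the CEPG/CPG fits are exercised on HWE data, which is valid
for nesting and null behaviour but does not probe their robustness
advantage), and ascertainment beyond affected-child/control-child.
Passing tests therefore demonstrate correctness of the estimator under
its own assumptions, not robustness to their violation.

## Recovery experiments and what "unbiased" means here

The test suite and the acceptance script rerun the published estimation
experiments at 500–1000 replicates. Per-replicate MLEs of ratio
parameters are right-skewed at these sample sizes (300–1600 family
units): for the five-parameter fit of the six-unit design, roughly one
replicate in ten places few two-copy mothers and drives $\hat S_2$ into
the 4–8 range, so the *mean* of $\hat S_2$ sits 10–20% above the
generating value while the *median* is on target (2.03 for $R_2 = 2$,
2.07 for $S_2 = 2$ at 500 replicates). The tests therefore assert
recovery by the median — the quantity a log-scale box plot displays —
within three Monte-Carlo standard errors; the acceptance script reports
plain means, as its experiment definitions prescribe. Multi-start refits
of the extreme replicates confirm they are true per-replicate optima, not
optimiser failures.

## Known limitations

* Autosomal biallelic SNPs only; no X-chromosome or sex-specific models.
* Larger pedigrees contribute through their extracted sub-units; no
  joint likelihood over extended families.
* One SNP at a time; no haplotype or LD-aware modelling.
* No permutation p-values or genomic control; raw tests only.
* Estimates on the positivity boundary are flagged but not corrected;
  chi-squared reference distributions are used throughout.
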