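---
title: "A subunit-competition model of allele-dosage penetrance"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A subunit-competition model of allele-dosage penetrance}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tetradose)
```

## The model

Plant cyclic nucleotide-gated channels (CNGCs) are tetramers.  When a
cluster of redundant CNGC genes expresses interchangeable subunits, a
gain-of-function point mutation in one of them — here called *brush*, a
constitutively Ca²⁺-leaky subunit — competes with the wild-type subunits of
the whole cluster for the four slots of every channel.  `tetradose`
formalises the resulting genetics.

The central quantity is the mutant subunit fraction

$$f = \frac{\text{expression-weighted mutant allele copies}}
           {\text{total expression-weighted allele copies}},$$

computed by `build_pool()`.  Under random assembly each slot of a tetramer
is an independent draw from the pool, so the composition of a tetramer is
multinomial with 4 trials, and the probability of the all-mutant
homotetramer is simply $f^4$.  With four equally expressed diallelic loci
(eight allele copies of weight 1):

* heterozygote: $f = 1/8$, homotetramer odds $f^4 = 1{:}4096$;
* mutant homozygote: $f = 1/4$, odds $1{:}256$.

Only the homotetramer is assumed active (all mixed tetramers are silent),
which is what makes a *gain-of-function* allele behave *recessively*: the
sixteen-fold drop in homotetramer probability between homozygote and
heterozygote is the phenotypic switch.

```{r}
het <- build_pool(genotype(BRUSH = c(WT = 1, brush = 1)))
odds_form(homotetramer_probability(het))
hom <- build_pool(genotype(BRUSH = c(brush = 2)))
odds_form(homotetramer_probability(hom))
```

## Assumptions, and what is configurable

**Equal expression.**  The four transcribed cluster loci (BRUSH and three
paralogs) default to weight 1 per allele copy; the fifth locus carries a
transposon insertion, produces no transcript, and is modelled as
unexpressed.  Relative expression of the four genes has not been measured
comparably, so equal weights are an explicit model assumption, not data;
`default_loci(weights = ...)` makes them configurable.

**Null alleles contribute nothing.**  A premature-stop allele is treated as
producing no assembly-competent subunit (no evidence of a poisoning
truncation product).

**Random mixing.**  Assembly ignores locus-specific pairing preferences;
interaction assays detect contacts among all subunit pairs tested, but
in-planta constraints are unknown.

**No biophysics.**  Conductance, gating and current–voltage behaviour are
out of scope; the model stops at "how many leaky tetramers".

## From tetramer odds to a phenotype call

A cell assembling $n$ tetramers (default $n = 64$, the illustrative
$8\times8$ grid; the true number of channels per cell is unknown and $n$ is
a sweep parameter) is called **mutant** when a penetrance statistic crosses
a threshold $\tau$.  The default statistic is the per-cell probability of
at least one leaky tetramer,

$$P_{\ge 1} = 1 - (1 - f^4)^n,$$

a cell-autonomous "hit" model; the expected leaky fraction $f^4$ is offered
as the alternative, since how much leaky channel a cell tolerates is not
known.  An `activity_rule(k)` generalises "leaky" to $\ge k$ mutant
subunits; the default $k = 4$ encodes silent heterotetramers, and $k < 4$
is exploratory only.

Six genotype/intervention observations constrain the parameterization:

```{r}
check_consistency(penetrance_model(tau = 0.1, n = 64))
```

The threshold $\tau = 0.1$ was chosen inside the feasible interval
separating the largest expected-wild-type statistic (heterozygote,
$\approx 0.0155$) from the smallest expected-mutant statistic (homozygote,
$\approx 0.2216$) at $n = 64$; `feasible_threshold_interval()` keeps that
calibration transparent rather than baked in.

**Intervention defaults.**  The overexpression transgene weight defaults to
8 — a strong constitutive promoter taken as comparable to the total native
cluster expression of eight allele copies; whether the real transgene
exceeds or trails that total is unquantified, so the weight is a parameter.
The RNAi retained-expression fraction defaults to 0.25: silencing is strong
but incomplete in the source experiments, which print no numeric value.
Both defaults are sweepable, and the native-promoter complementation
failure is naturally explored as a low-weight (≤ 2) transgene variant of
scenario 3 rather than asserted as a seventh constraint, because it is
attributed to expression level without quantification.

## Monte Carlo

`simulate_cell()` draws one cell.  *Infinite-pool* mode draws each tetramer
independently (the analytic model's sampling counterpart).  *Finite-pool*
mode takes the $8\times8$ grid literally: frequencies are converted to
integer subunit counts summing to $4n$ by largest-remainder rounding (ties
broken by class order, deterministically) and a uniformly random partition
into $n$ unordered 4-subsets is drawn, so subunits are conserved exactly.
The two modes are compared in the tests, not conflated: the finite-pool
marginal converges to the multinomial as $n$ grows.

`simulate_cells()` scales to many cells by drawing each tetramer's mutant
count from its exact Binomial$(4, f)$ marginal instead of storing full
compositions — a mathematically identical shortcut for leaky-count
statistics, used for the convergence checks (10⁵ cells of 64 tetramers run
in well under a minute).  All generators take a seed and reproduce
byte-identical output under it.

```{r}
counts <- simulate_cells(pool_from_fraction(1 / 4), 1e4, seed = 1)
c(mean = mean(counts), analytic = 64 / 256)
```

## qPCR quantification and the knockdown bridge

`delta_delta_ct()` implements Livak's $2^{-\Delta\Delta C_T}$ method with
amplification efficiency fixed at 2 (no efficiency correction is applied;
Pfaffl-style calibration is out of scope).  Technical replicates are
averaged on the $C_T$ scale before any delta is formed, and
$\Delta\Delta C_T$ is referenced to the mean control $\Delta C_T$ — the
source protocol normalises to empty-vector control roots without stating
the aggregation, so the mean is used and documented.  The summary fold is
$2^{-\overline{\Delta\Delta C_T}}$, i.e. the geometric mean of replicate
folds: aggregation stays on the cycle scale throughout, which avoids the
upward Jensen bias an arithmetic mean of folds acquires under Gaussian
$C_T$ noise.  `fold_to_knockdown()` maps a measured fold to a retained-
expression fraction (clamped at 1, flagged), closing the loop from Ct table
to phenotype call.

## Synthetic data

The generators emulate the *shape* of the source experiments, with sizes
matching them: qPCR with 6 biological × 3 technical replicates, Gaussian
noise on the cycle scale (technical sd 0.1, biological sd 0.5 — a shared
per-sample shift affecting both genes, which the ΔΔCt design cancels), and
per-plant infected-nodule counts for 10 plants per construct.  Nodule means
are user-set (wild-type/rescued 8, mutant 0.2 by default) because no
numeric means are printed for the real data; Poisson is the default count
model with a negative binomial offered for the overdispersion real counts
show.  Passing tests therefore demonstrate parameter recovery under the
generator's own error model — they say nothing about instrument effects,
efficiency drift, or non-Gaussian Ct error in real qPCR data.

## Numerical choices

* **Exact rational arithmetic.**  Pool frequencies and multinomial masses
  are carried as reduced integer fractions whenever the inputs are rational
  (numerators/denominators as integer-valued doubles, exact below 2⁵³, with
  automatic fallback to floating point beyond), so printed odds like
  1:4096 are bit-exact, and the denominator-≤ 8 pool sweep matches
  exhaustive draw enumeration identically.
* **Degenerate inputs.**  An all-null or unexpressed configuration raises
  an explicit empty-pool error; a zero probability renders as infinite odds
  through a typed condition rather than a string `"Inf"` deep in the model.
* **Problem sizes.**  Test and acceptance simulations use 10⁵ cells for
  convergence checks, 1000 replicate simulations for fold recovery, and
  exhaustive enumeration up to denominator 8 — all chosen to leave Monte
  Carlo error well below the 3-standard-error acceptance bands on a single
  CPU.

## Known limitations

The model is deliberately minimal: no transcriptional regulation, protein
stability, trafficking or tissue structure; no temperature dependence
(the phenotype is described at 26 °C); no partial activity of mixed
tetramers beyond the exploratory `k < 4` rule; and the penetrance threshold
is a phenomenological device, not a measurement of cellular calcium
tolerance.  Scenario agreement shows that one parameter set *can* explain
all six observations — it does not identify the parameters, and the
feasible-τ interval makes the breadth of that non-identifiability explicit.
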