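---
title: "Inferring invasion routes from barcode haplotypes with ABC"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring invasion routes from barcode haplotypes with ABC}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(abcroutes)
```

## The problem

When an invasive species is detected far from its native range, the first
question is *where did it come from* — a native source, or an already
established invasive population acting as a bridgehead? With a single
maternally inherited barcode locus (here the ~685 bp mitochondrial CO1
fragment), classical summary comparisons rarely separate these hypotheses.
`abcroutes` implements the likelihood-free route: each candidate invasion
history is written down as an explicit demographic **scenario**, data are
simulated under every scenario with parameters drawn from priors, and the
scenarios are scored by how often their simulations resemble the observed
data — Approximate Bayesian Computation (ABC) scenario choice. The package
ships the scenario configurations of a worldwide analysis of the brown
marmorated stink bug (*Halyomorpha halys*), whose CO1 dataset spans ten
countries, 916 sequences and 57 haplotypes.

## The model, stage by stage

### Haplotypes

Aligned sequences are collapsed to haplotypes by exact string identity
(case-insensitive; `N` and `-` match only themselves — no wildcard
expansion, which keeps the partition deterministic and conservative).
Labels are `H1, H2, ...` in order of first appearance, overridable by a
user label map so existing numbering conventions can be preserved. The
packaged worldwide count table stores counts per locality; asterisked
localities in the published table lack per-locality haplotype resolution
and are stored at the finest level consistent with the country totals.

### Statistical-parsimony (TCS) networks

Haplotypes are connected in increasing mutational-step order up to a
**parsimony connection limit**. The limit is the largest number of observed
differences `j` for which the probability of "no homoplasy" is at least
95%. The published formulation of that probability leaves numerical
details open, so the package uses an explicit finite-sites model stated in
full: mutations strike the `m` sites independently and uniformly; given `j`
differing sites, the probability that the true number of mutations `K`
equals `j` (no site hit twice) is the posterior under a truncated uniform
prior on `K` over `j .. j + 200`. The occupancy probabilities
`P(J = j | K)` are computed by a forward recursion on the number of
occupied sites; the test suite recomputes them independently from the
Stirling-number closed form and by Monte Carlo. For `m = 685` and 95%
confidence the limit evaluates to 7 steps. Network assembly is the
minimum-spanning-network rule: within one step class, every pair joining
components that were distinct before the class is connected (equal-step
alternatives are retained as loops, matching the union of all minimum
spanning trees — a property the tests verify by exhaustive enumeration);
multi-step connections insert `steps - 1` zero-frequency intermediate
nodes.

### Scenarios and priors

A scenario is a backward-time demographic program: populations with
haploid effective sizes (mtDNA is maternally inherited, so sizes are
effective numbers of transmitting females), merge events (`child` lineages
move into `parent`), admixture events (each child lineage goes to one of
two parents with probability `r`), and optional size changes. Inequality
conditions (e.g. every introduced size below every native size, or event
`A` more recent than event `B`) are enforced by rejection sampling.

Default priors, used by all shipped configurations:

| parameter | prior | units |
|---|---|---|
| effective sizes `N_*` | Uniform[10, 10000] | haploid individuals |
| event times `t_*` | Uniform[10, 10000] | generations |
| admixture rate `r` | Uniform[0.001, 0.999] | — |
| mean mutation rate | Uniform[1e-7, 1e-5] | per site per generation |
| locus rate | Gamma(shape 2, mean = drawn mean) | per site per generation |
| mean kappa (C/T) | Uniform[1.5, 20] | — |
| locus kappa | Gamma(shape 2, mean = drawn mean) | — |

The size and time defaults mirror the defaults of the standard ABC
software for this analysis family; the admixture prior is the widest
proper uniform. No calendar constraint (detection years) is imposed on
event times — the shipped configurations order events only through their
inequality conditions.

### Coalescent simulation and mutation

Genealogies follow the structured haploid coalescent: within a population
of size `N`, `k` lineages coalesce at rate `k(k-1)/(2N)`; demographic
events move lineages between populations at their drawn times. Mutations
follow HKY with unequal base frequencies and transition coefficient kappa,
10% invariant sites, and continuous per-site gamma(shape 2, mean 1)
relative rates (continuous rather than 4-category discretisation: exact
and simpler for simulation). The rate matrix is normalised so one unit of
`rate` equals one expected substitution per site per generation at
stationarity. Substitutions are simulated exactly (thinning at the
dominating exit rate), so multiple hits at one site occur naturally; base
frequencies default to the empirical composition of the observed
alignment, a common ABC practice, and are configurable.

### Summary statistics

The rejection space uses the single-locus DNA panel: per population the
number of distinct haplotypes, segregating sites, mean and variance of
pairwise differences, and private segregating sites (segregating within
the population, at most one base across all others); per population pair
the mean cross-population differences, the pooled haplotype count and a
Hudson-style FST `1 - pi_w / d_xy`. `pi_w` uses the with-replacement
(denominator `n^2`) within mean so that two identically composed samples
give exactly 0; FST is reported missing (not 0) when `d_xy = 0`. Sites
with `N`/`-` are masked pairwise. The exact statistic panel behind the
published analysis is not recoverable from the text, so the panel is
configurable with this default.

### Rejection, posteriors, diagnostics, confidence

Every statistic is imputed (reference-table column mean, which becomes 0
after standardisation) and standardised by the reference-table mean and
standard deviation; zero-variance statistics are dropped with a warning.
The `ceiling(tolerance * n)` rows closest to the observed vector in
Euclidean distance are retained (default tolerance 1%, i.e. 10,000 of the
full-scale 1,000,000 rows; the full-scale row count follows the published
run length, and both knobs are configurable). Posterior probabilities come
either from retained-set proportions with Clopper–Pearson intervals
(`direct`) or from a multinomial logistic regression of the scenario label
on the standardised statistics centred at the observed point, evaluated at
that point, with delta-method intervals on the fitted coefficients
(`logistic`, the headline estimate). Near-separation triggers a
ridge-regularised refit, flagged in the diagnostics.

Before trusting a posterior, `prior_scenario_check()` projects the
observed vector into the PCA of the simulated statistics and reports
whether it falls inside the central 99% box of the leading components,
plus per-statistic tail probabilities starred at two-sided 5% / 1% / 0.1%
— many three-star statistics mean the scenario/prior combination cannot
reproduce the data. Confidence in scenario choice is **posterior-based
error** implemented as a posterior-predictive reclassification rate:
simulate `n_pods` datasets (default 500) from the selected scenario with
parameters resampled from its retained draws, push each through the full
rejection + posterior pipeline against the same reference table, and
report the fraction assigned back to the selected scenario. The published
text does not pin down whether its confidence is this rate or a
type-I-style complement; the reclassification rate is the implemented,
documented choice, and the number of PODs is configurable.

When many scenarios are compared at once, `run_elimination_round()`
reproduces the two-round procedure: scenarios below a 0.10 posterior
probability are dropped and the analysis re-runs on the survivors (whose
probabilities again sum to 1).

## Reproducibility and numerical choices

Every stochastic stage takes an explicit integer seed. Bulk stages derive
one child seed per unit of work (reference-table row, pseudo-observed
dataset) by counter-based splitting (`derive_seed()`), so results are
bit-identical regardless of evaluation order or how rows would be
distributed across workers. Rejection ties are broken by row index;
network ties by lexicographic label order; event-time ties by input order.
Degenerate inputs are defined, not patched around: a single-sequence
population reports missing pairwise statistics and zero segregating sites;
identical monomorphic populations report missing FST; scenarios whose
conditions are (near-)unsatisfiable abort after a configurable number of
rejections.

## What the synthetic generator emulates — and what it does not

`synthetic_experiment()` and `generate_study()` produce study-shaped data:
three native populations joined by ancient divergence, introduced
populations founded by recent bottlenecked divergence (founder sizes
10–500 against native 1000–10000), 685 bp alignments, and count tables
with one dominant haplotype per introduced population and a long rare tail
in natives (`table1_like_counts()`). They reproduce the *structure* that
drives the inference — founder-effect diversity loss, source/bridgehead
contrasts — with known ground truth. They do not emulate real CO1 base
composition or selection, PCR/sequencing error, geographic substructure
within populations, or the actual GenBank haplotype sequences; passing
tests therefore demonstrate that the machinery is correct and calibrated,
not that any particular biological conclusion follows from real data.

Test and acceptance runs use reduced problem sizes chosen as the package's
own defaults for routine verification: alignments of 100–400 sites, sample
sizes 10–30 per population, reference tables of 10,000–50,000 rows
(scenario recovery uses 50,000), 10,000 replicates for the pairwise
coalescence-time calibration and 5,000 for the diversity calibration. The
full-scale defaults (685 sites, observed sample sizes, 1,000,000 rows, 500
confidence PODs) remain the configuration defaults.

## Known limitations

* Single-locus, haploid inference: posterior contrasts can be genuinely
  weak (the shipped California experiment is the canonical example), and
  the method reports that honestly through wide intervals and low
  confidence rather than resolving it.
* No recombination (appropriate for mtDNA) and no continuous migration:
  gene flow is representable only through discrete admixture events.
* ABC parameter estimation (posteriors on sizes/times beyond scenario
  choice) is out of scope.
* The agglomerative network retains all equal-step alternatives as loops;
  it does not apply frequency- or topology-based loop breaking.
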