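---
title: "Models and methods: analysing lytic phage–host copropagation experiments"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods: analysing lytic phage-host copropagation experiments}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(coevo)
```

# The experimental system

A serial-passage coevolution experiment pairs a bacterial host with a lytic
phage in a well-mixed liquid culture. Every day the coculture is diluted
into fresh medium (copropagation regime), or the phage are filtered away
from the cells and used to infect a fresh ancestral host culture
(phage-only regime). Densities are tracked as CFU/ml (viable cells),
PFU/ml (infectious phage), and OD600 (biomass); populations are sequenced
at intervals, and each variable site is scored per population as *absent*
(ancestral base), *polymorphic* (segregating), or *fixed* (evolved base).

`coevo` implements the complete quantitative calculus of that design:
generation bookkeeping, fitness statistics, infection/adsorption kinetics,
the polymorphism-weighted mutation-accumulation analysis, and the
inferential battery, plus a mechanistic simulator that generates all of
those inputs with known ground truth.

# The within-day infection model

`simulate_within_day()` integrates susceptible cells $S$, staged infected
cells $E_1 \dots E_n$, and free phage $P$ (all per ml):

$$
\frac{dS}{dt} = \mu S\Big(1 - \frac{S+I}{K}\Big) - kSP, \qquad
\frac{dE_1}{dt} = kSP - \delta E_1, \qquad
\frac{dE_i}{dt} = \delta (E_{i-1} - E_i), \qquad
\frac{dP}{dt} = b\,\delta E_n - kSP,
$$

with $I = \sum_i E_i$ and OD600 $= (S+I)\cdot$`od_per_cell`.

Assumptions worth stating explicitly:

* **Logistic growth to a nutrient-limited plateau.** Growth stops at the
  carrying capacity $K$; infected cells occupy carrying capacity but do
  not divide.
* **Mass-action adsorption.** Phage attach at rate $kSP$; every
  adsorption removes one free phage. $k$ is stored in ml/cells/min as the
  field reports it and converted to per-hour ($\times 60$) in one place.
* **Erlang latent period.** The latent period $\tau$ is realised as
  $n = 5$ sequential stages with per-stage rate $\delta = n/\tau$. A
  single-stage (exponential) latent period would let some cells burst
  unrealistically early; five stages reproduce the observed lag between
  infection and the rise of free phage without a delay-differential
  solver.
* **Stationary refractoriness.** When `stationary_refractory = TRUE`
  (default), adsorption is shut off once total cells reach 95% of $K$,
  reflecting that stationary-phase cells are not productively infected.
* **Partial resistance as reduced adsorption.** A resistant host variant
  multiplies $k$ by `resistance_factor` $\in (0,1]$; it is not modelled
  as absolute immunity, matching the mechanism suggested by adsorption
  assays on evolved hosts.

## Parameters, units, defaults

| parameter | unit | default | rationale |
|---|---|---|---|
| `mu` | 1/h | 0.382 | ancestral-host specific growth rate in minimal glucose medium |
| `carrying_capacity` | cells/ml | 3e8 | glucose-limited plateau (OD600 ≈ 0.4) |
| `od_per_cell` | OD per cells/ml | 0.4/3e8 | plateau conversion; a parameter because the OD/CFU ratio can drift over long experiments |
| `k_ads` | ml/cells/min | 1.4e-9 | adsorption rate constant of the ancestral pairing |
| `latent_period` | h | 1 | time from adsorption to burst |
| `n_latent` | — | 5 | Erlang shape (see above) |
| `burst_size` | phage/cell | 416 | calibrated, see below |
| `resistance_factor` | — | 1 | ancestral host |
| `stationary_refractory` | — | TRUE | no infection at the plateau |

**Burst-size calibration.** The burst size is the one parameter the
within-day data do not pin down directly. `tune_burst_size()` bisects it
(amplification is monotone in $b$) so that a phage-only passage — host at
$2\times10^7$ cells/ml with $\mu = 0.46$/h, phage at $10^7$ PFU/ml
(MOI 0.5), six hours — amplifies free phage 1,000-fold, the regime's
characteristic amplification. The calibrated value, 416 phage per lysed
cell, sits comfortably inside the range reported for small lytic RNA
phage, and is the package default.

## Numerics

The deterministic mode integrates with `deSolve::lsoda` (`rtol = 1e-9`)
sampled on a fixed 0.01 h grid. An explicit fixed-step scheme looks
attractive for reproducibility, but the adsorption term makes the system
stiff exactly where the biology is interesting: once phage reach
$\sim10^{11}$/ml the per-cell adsorption rate is $\sim10^4$/h and an
explicit fixed-step method at any practical step size oscillates into
negative densities and NaN. `lsoda` handles the stiff phase and is well
below the $10^{-6}$ relative accuracy the test-suite demands on the
phage-free logistic closed form. Tiny integrator undershoots below zero
are clipped to zero.

The stochastic mode is a tau-leap on particle counts in `volume_ml`
(default 3 ml): per step of the same grid, births, adsorptions, stage
transitions, and bursts are Poisson draws at the deterministic rates,
clamped so no compartment goes negative. One integer seed makes a run
bit-reproducible. The tau-leap mean carries an $O(\Delta t)$ bias, so it
is validated against the ODE in a *small-count* regime (hundreds of
particles, grid 0.002 h, 200 seeds), where demographic noise dominates
that bias; at realistic lab densities ($10^7$–$10^8$/ml) Poisson noise is
negligible relative to any finite-step bias, and no finite number of
seeds could separate the two.

# Serial passages

`run_serial_passages()` chains days. In the copropagation regime the
whole culture (cells, infected cells, phage) is diluted to a target
starting OD (default 0.05, ~8-fold from the plateau); in the phage-only
regime the cells are discarded daily, the phage diluted to the protocol's
infection titre, and fresh ancestral cells supplied. The initial density
of day $d{+}1$ equals the final density of day $d$ divided by that day's
dilution factor — exactly the relation the generation bookkeeping inverts
when a passage log omits initial densities. A population below one
particle per culture volume is recorded as an extinction *event*, never
an error.

**The long-run coexistence scenario.** Because the latent period (~1 h)
is much shorter than the daily susceptible window, within-day phage
amplification is multi-cycle and therefore exponential in the burst size.
With the ancestral pairing (burst 416, full adsorption) the host is
exterminated within a day — which is what the ancestral pairing does in
reality too. Stable long-term copropagation requires the configuration
the experiment itself converged to: a partially resistant host
(`resistance_factor = 3e-4`) facing a reduced-virulence phage.
`coexistence_scenario()` packages that pairing with burst size 40, chosen
once at design time: it sustains both populations for ≥54 daily passages
with phage amplification of 6.5–7.2-fold per day, inside the 2–20-fold
band such experiments report, while the host stays at its plateau.
Larger bursts (≥50) tip the deterministic daily map into predator–prey
overshoot and crash the host; smaller ones (≤30) lose the phage to
dilution.

# The substitution process generator

`simulate_mutation_history()` provides ground truth for the
mutation-accumulation estimators. Sites arise as a Poisson process at
`rate_per_base_per_generation` × genome length, scaled per gene by
`gene_rate_multipliers`; each new site is *polymorphic* for
`polymorphic_dwell` generations, then *fixes* or (with
`reversion_prob`) reverts to *absent*. Statuses are read off at the
requested sampling generations, and never-observed sites are dropped, as
in a real sequencing table. The generator deliberately does **not**
model sequence-level evolution (only site statuses), linkage or clonal
interference between sites, selection coefficients, or spatial structure
— so parameter-recovery tests demonstrate estimator correctness, not
robustness to those real-data features.

# Counting conventions

* **Weights.** absent = 0, polymorphic = 0.5, fixed = 1
  (`status_weight()`).
* **Cumulative accumulation.** Between consecutive sequenced populations
  of a lineage, each site contributes $|\Delta \text{weight}|$
  (`cumulative_mutation_series()`). One rule covers all trajectories:
  appearance and fixation scores 1, de-fixation to polymorphic 0.5, loss
  of a polymorphic site 0.5 — so a fix-then-revert trajectory scores on
  every leg (1, 0.5, 0.5).
* **Heterogeneous founders.** A site polymorphic in the ancestral stock
  starts at weight 0.5 and contributes a further 0.5 when it fixes; this
  follows directly from the weight definition.
* **Fixation rate.** Final cumulative count / (genome length × the
  lineage's final generation total); group mean ± sample SD across lines,
  and the ratio of group means (`lineage_rate_summary()`). On the bundled
  study table this yields per-line counts 7.5/7.0 (copropagation lines)
  and 2.0/2.5 (phage-only lines), group means 1.05×10⁻⁵ and 3.17×10⁻⁶
  per base per generation, and a ratio of 3.31.
* **Gene bias.** `gene_bias_binomial()` tallies weighted counts inside a
  gene against the total. Two tallies exist: summing the cumulative
  $|\Delta w|$ increments over the chosen lineages (default), or summing
  the final population weights. The cumulative tally is the one
  consistent with the accumulation analysis — on the bundled table it
  places 9.5 of 14.5 weighted copropagation mutations (65.5%) in the A2
  gene — and is therefore the default. Half-integer counts are doubled
  (19/29) for the exact test, which preserves the observed fraction;
  plain half-up rounding is available behind `half_integer = "round"`.
* **A2 boundaries.** The gene map places A2 at genome positions 61–1323:
  the start follows from the printed offset between gene and genome
  positions, and the 1,263-nt length makes the CDS 29.95% of the
  4,217-base genome, consistent with the quoted "30%". The binomial null
  uses the exact 0.2995, not the rounded figure.

# Codon annotation

`annotate_mutation()` maps a genome position into every overlapping gene
(the read-through A1 shares the coat start codon, so a coat-region site
yields one record per gene), computes the 1-based gene position,
codon index $\lceil p/3 \rceil$, and translates ancestral vs mutant
codons. A substitution turning an AUG start into an alternative initiator
(GUG, UUG, …) is classed synonymous with change Met→Met, since
initiation still delivers formyl-Met. The bundled reference sequence is
**synthetic**: a fixed-seed random background with the published codon
context embedded at every tabulated site, sufficient for exact codon
annotation of those sites but not a real genome.

# Estimators and their numerical behaviour

* **Semi-log rates.** OLS of $\ln(\text{value})$ on time; $r^2$ is the
  squared Pearson correlation on the log scale. Zeros are excluded with a
  message, never imputed. Slopes are invariant to rescaling of the
  values.
* **Growth-rate windows.** On a logistic curve the semi-log slope
  estimates $\mu(1 - \bar S/K)$ averaged over the window, so it is biased
  low by roughly the mean of $S/K$ across the fitted points: a window
  reaching $K/4$ under-recovers $\mu$ by 5–15% depending on the inoculum.
  The default window (maximal prefix below 40% of the plateau) matches
  common practice for fitting growth curves but inherits that bias;
  recovery tests therefore use inocula near $K/1000$ with windows capped
  at $K/20$, where the bias is ~1%. The window actually fitted is always
  reported in the `rate_fit`.
* **Time to stationary.** Plateau = mean of the last three points;
  reported time is the linear interpolation of the first crossing of
  $(1-\varepsilon)\cdot$plateau. A series still rising over its final 10%
  span (or past a peak) is rejected rather than extrapolated.
* **Adsorption constant.** $k = -\text{slope}(\ln P \text{ vs } t)/C$
  with $t$ in minutes; exact on noiseless decays, and its product with
  the cell density equals minus the per-minute semi-log slope by
  construction.

# The inferential battery

Standard machinery is delegated to the standard implementations —
`aov`, `TukeyHSD`, `t.test`, `lm`/`anova`, `emmeans::emtrends`, `ppois` —
behind stable result containers. Choices the interfaces fix:

* **Tukey vs Tukey–Kramer** is selected automatically by group-size
  equality (that is what the studentized-range machinery does with
  unequal $n$); the variant used is reported, and the studentized-range
  statistic $q$ is attached per pair.
* **ANCOVA** fits `y ~ x * group` on log-scale responses; the
  interaction F (df = groups − 1, N − 2·groups) tests slope homogeneity,
  implying pointwise observations entered individually — the layout that
  reproduces the degrees of freedom such analyses report. Pairwise slope
  contrasts use the pooled residual variance with Tukey adjustment.
* **Exact binomial, two-tailed,** uses the minimum-likelihood convention:
  the p-value sums all outcome probabilities not exceeding that of the
  observed count (relative tie tolerance 1e-12). It is written directly
  from the pmf so tests can verify 1e-12 agreement with an independent
  enumeration oracle; `binom.test` is used as a second, independent
  cross-check.
* **Slope t-test:** $t = (b_1 - b_2)/\sqrt{se_1^2 + se_2^2}$ with
  $df = n_1 + n_2 - 4$, two-tailed.
* **Welch's t** with Satterthwaite df; two degenerate zero-variance
  groups with equal means return $t = 0$, $p = 1$ by convention.
* **Replicates are never pooled silently.** Fitness grids keep every
  replicate; any summary (e.g. the mean entering a grid cast) is an
  explicit, visible choice of the caller.

**Calibration testing.** The suite checks every test's type-I error on
1,000 simulated null datasets against a ±2 standard-error band (the
discrete exact binomial against its attainable size, since a discrete
test cannot attain 0.05 exactly). Because a correctly calibrated test
lands outside a 2-SE band in about 5% of batches, an out-of-band batch is
confirmed on one independent 1,000-draw batch before the check fails —
a genuinely miscalibrated statistic fails both batches, while the false
alarm rate drops to ~0.25%.

# Problem sizes used by the test-suite

Chosen so the full suite carries real statistical power while staying
lightweight: 200 seeds for the tau-leap/ODE mean comparison (small-count
regime), 100 seeds for adsorption and fixation-rate recovery, 300–500
seeds for the gene-multiplier mixture fraction, 1,000 null datasets per
calibration batch, and 50–54-day deterministic serial-passage runs.

# Known limitations

* The ODE model has no explicit nutrient state: growth limitation is
  carried entirely by the logistic term, so diauxie or death phases are
  out of scope, as is intracellular replication detail.
* Resistance is a single multiplicative adsorption factor; surface-
  receptor heterogeneity within a population is not modelled.
* The effective-population-size helper is deliberately simple arithmetic
  (inoculum × infecting fraction); it quantifies a per-passage bottleneck,
  not a full coalescent-effective size.
* The simulator's mutation process treats sites independently; estimates
  of uncertainty on real data with strong linkage will be optimistic.
* `cumulative_generations()` reproduces the standard estimator exactly,
  including its known underestimation of cell generations while lysis is
  removing cells — no correction is applied.
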