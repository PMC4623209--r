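---
title: "Modelling subconductance gating of single SR K+ channels"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling subconductance gating of single SR K+ channels}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", fig.width = 6)
library(subkinetics)
```

## The problem

Sarcoplasmic-reticulum K+ channels (the TRIC-B subtype in particular) are
voltage-regulated channels that open predominantly to *subconductance*
levels: stable open states carrying less current than the fully open pore.
In planar-bilayer recordings the channel shows a closed level (0 pS), four
sublevels at roughly 60, 93, 121 and 161 pS, and a full open level at
199 pS, with trains of brief (~2 ms) sublevel events flanking full opening
bursts. Two modelling questions follow:

1. **Kinetics.** Which aggregated Markov gating scheme describes the
   sublevel/full-open interplay and its voltage sensitivity?
2. **Identity of the sublevels.** Are the sublevels genuine conductance
   states, or could they be an artifact of *fast gating* — full open/closed
   flicker too rapid for the recording bandwidth, which after low-pass
   filtering masquerades as an intermediate level?

`subkinetics` implements the complete analysis chain needed to pose and
answer these questions on simulated data: gating-model construction,
stochastic simulation through a realistic acquisition chain, segmental
k-means idealization, dwell-time and rate-constant estimation with
missed-event correction, and model discrimination by the Earth Mover's
Distance (EMD) between amplitude distributions.

## Gating models

A `gating_model` couples Markov states, each assigned to a conductance
class, with a map of directed rates (s^-1). Rates are per-voltage
constants: voltage dependence is represented by fitting rates independently
at each holding potential, not by a parametric rate(V) law, because
per-voltage fits are all the data constrain.

The candidate schemes (`build_preset()`):

* **M1** — one state per conductance level (C, S4..S1, O), all-to-all.
* **M2** — closed / merged substate / open. The merged class `S` sits
  midway between closed and full open (99.5 pS) and carries a fixed
  open-channel noise of half its amplitude: it represents a *spread* of
  sublevels by one broad level.
* **M1_reduced** — the linear chain C3–C2–C1–S4–S3–S2–S1–O1–O2: three
  closed and two full-open states (the minimum implied by multi-component
  closed/open lifetime distributions), one Markov state per sublevel, and
  only the consistently observed transitions.
* **M1_adapted** — the same nine states with all discarded edges retained.
* **M2_adapted** — C3–C2–C1–S–O1–O2 without direct O–C edges.
* **fast_gating** — no sublevel states at all: four closed/open couplets
  C_Sx/O_Sx spliced into the slow chain, flickering with a fast closing
  rate alpha = 50,000 s^-1. A couplet with opening rate beta spends a
  fraction beta/(alpha+beta) of its sojourn open, so after filtering it
  appears as a sublevel of conductance 199 * beta/(alpha+beta) pS. The
  opening rates 21,583 / 43,868 / 77,564 / 211,842 s^-1 reproduce the four
  sublevels exactly. The slow chain rates are shared with `M1_reduced`;
  because the couplet anchor is occupied for only part of each sojourn,
  this scheme systematically overestimates apparent sublevel dwells and
  occupancies — an intrinsic deficiency of the fast-gating explanation,
  not an implementation choice.

**Preset rate values.** The study this package is motivated by reports its
fitted rate constants only in figure artwork, so preset defaults are
documented placeholders, chosen once on scientific grounds: substate exit
rates are set so mean sublevel dwells are 1.7/2.3/2.1/1.9 ms for
S1/S2/S3/S4 (the reported means); closed and open blocks use well-separated
lifetime components (~2/20/250 ms closed, ~7/40 ms open), consistent with
multi-exponential lifetime distributions. The separation is also a design
requirement of the synthetic testbed: rate constants of states hidden
inside an aggregate are statistically identifiable from dwell sequences
only when their timescales are distinguishable at realistic event counts.

```{r presets}
m <- build_preset("M1_reduced", voltage = 30)
m
class_po(m)
```

`q_matrix()` gives the generator; `stationary_distribution()` solves
pi Q = 0 by the null space of t(Q), after verifying strong connectivity of
the positive-rate graph; `class_po()` aggregates occupancy by conductance
class.

## Simulation and the acquisition chain

`sample_path()` draws continuous-time trajectories with the Gillespie
direct method (exponential dwells, jump probabilities proportional to
rates; the inner loop is compiled, using R's RNG so runs are reproducible
under a seed). `acquisition_chain()` turns a path into a realistic sampled
recording:

* **standard** mode (explicit-sublevel models): render at 100 kHz
  (current = conductance x voltage, left-closed sample convention), add
  per-class fixed open-channel noise and Gaussian baseline noise,
  Gaussian-filter at 1 kHz, resample at 10 kHz.
* **fast_gating** mode: render at 400 kHz, filter at 10 kHz and resample at
  100 kHz (emulating digitization of unresolved flicker), then add noise,
  filter at 1 kHz and resample at 10 kHz as for acquired data.

The Gaussian filter kernel has SD sigma_t = 0.1325/fc, the value that puts
the -3 dB point exactly at fc; it is truncated at +/-4 sigma and
renormalized, so DC gain is exactly 1. (The commonly quoted 10–90% rise
time 0.3321/fc is a rounded convention; the exact erf-step value for this
kernel is 2.5631 sigma_t = 0.3396/fc, which is what the tests assert.)
Decimation picks every k-th sample — the Gaussian stage is the anti-alias
filter — and upsampling is sample-and-hold.

**Baseline noise.** The emulated recordings do not come with a stated noise
level. `noise_sd` is defined *at the analysis bandwidth* (after the 1 kHz
filter): broadband noise inserted at the acquisition rate is inflated by
the filter stage's known white-noise attenuation so the conditioned trace
carries the requested SD. The default is 0.05 x the full-open amplitude.
This value is bounded above by the data the generator emulates: the four
sublevels are individually resolvable in the recordings (they were
idealized with six amplitude classes, and per-sublevel amplitude
distributions are distinguishable), which requires the noise SD to be well
below the minimum inter-level spacing (0.14 x full-open amplitude). At
0.1 x full-open the sublevels merge into a single broad hump and the
study's own analysis would have been impossible.

## Idealization and dead time

`skm_idealize()` implements segmental k-means: Viterbi decoding of a
Gaussian-emission aggregated HMM (one emission class per conductance class)
alternated with re-estimation of class means, noise SDs (except classes
flagged `fixed_noise`, such as the deliberately broad merged substate) and
transition probabilities. Emissions are treated as independent samples —
filter-induced correlation is ignored in the likelihood, as is standard for
this algorithm. Class identity is anchored by the initial amplitude
ordering. `fixed_mean = TRUE` holds class amplitudes at their nominal
values, the appropriate mode when the level set is known a priori (e.g.
measuring the apparent level of a fast-flicker couplet, where free
re-estimation would let empty neighbouring classes drift onto the single
occupied level).

`apply_dead_time()` removes events shorter than the 0.6 ms resolution
limit by merging them into a neighbour, rescanning until all events are
resolvable; it is idempotent and never increases the event count. Two merge
conventions are provided: `"nearest"` (conductance-proximity, the default:
a brief flanked event most plausibly belongs to the nearer level) and
`"preceding"` (always extend the preceding dwell, the classic
apparent-dwell bookkeeping). On the chain topologies studied here the
nearest rule also pairs better with the first-order missed-event
correction — it preserves sublevel transition structure that
preceding-extension folds into the flanking dwells — so the default is
used throughout, including before rate fitting.

`compute_po()`, `po_diary()`, `mean_class_currents()` and
`transition_counts()` provide the per-class occupancy, stability diary
(default 5 s windows), current decomposition and transition-frequency
matrix (exportable for chord-diagram tools).

`apparent_sublevel_conductance()` measures the conductance of a
single-sublevel record (such as an isolated flicker couplet) as the mean
current of the whole idealized sojourn. The idealization verifies that one
substate class dominates; averaging over the full sojourn rather than over
sublevel-classified samples avoids the +/-3–6% boundary-truncation bias
that class-masked means suffer when filtered-noise excursions longer than
the dead time are captured by neighbouring classes.

## Dwell-time analysis

`log_binned_histogram()` bins durations logarithmically (10 bins per
decade) with a square-root-count ordinate. `fit_exp_mixture()` maximizes
the likelihood of a k-component exponential mixture left-truncated at the
dead time (each component renormalized by exp(t_d/tau)); optimization runs
in log-tau/softmax coordinates with analytic gradients from a deterministic
quantile grid plus seeded random restarts. For k = 1 the maximum-likelihood
estimate has the closed form mean(t) - t_d, which the numerical optimum
reproduces to ~1e-9. `select_component_count()` adds components while the
likelihood-ratio statistic exceeds the chi-squared(2) critical value at
P = 0.95, refusing degenerate candidates (coincident taus or vanishing
areas — structure below the resolvable limit).

## Rate estimation (MIL) with missed-event correction

`mil_loglikelihood()` evaluates the aggregated-Markov interval likelihood
of an idealized dwell sequence. The generator is partitioned by conductance
class; a dwell of duration t in class a propagates the state vector through
the within-class block and each observed class transition applies a
coupling block. Missed events are handled by a first-order correction of
the generator:

* within-class: excursions out of class a returning within t_d are folded
  in, `Q'_aa = Q_aa + Q_ac (I - expm(Q_cc t_d)) (-Q_cc)^-1 Q_ca` (c = the
  complement of a, evaluated via the inverse-free augmented-exponential
  integral so it is defined even at degenerate rate values);
* coupling for an observed a -> b transition: the direct jump plus
  unresolved excursions through the remaining classes, times a
  detectability factor `expm(Q_bb t_d)`;
* the dwell factor is `expm(Q'_aa (t - t_d))`, so total time is conserved,
  and the corrected likelihood converges to the uncorrected one as
  t_d -> 0.

The coupling deliberately uses the *uncorrected* within-class block in the
detectability factor: with the corrected block, virtual returns make the
factor nearly conservative at extreme rates, the decay penalty vanishes and
the likelihood diverges to the rate bounds. On data with 0.6 ms dead time
and rates around the study's sublevel speeds (t_d x rate ~ 0.3), the
residual estimator bias of this first-order scheme is below 15% per edge;
exact missed-event asymptotics are out of scope.

Propagation is eigendecomposition-based with a no-throw scaling-squaring
fallback, rescaled every step, with the dominant eigenvalue factored out so
no parameter region underflows: the surface stays finite and smooth, which
the quasi-Newton optimizer (`fit_rates()`, L-BFGS-B in log-rate space with
box bounds 1e-3 to 1e6 s^-1, restarted until the objective stops
improving) requires. Starting points are a moment-based initialization
(class-level counts over class time) and the model's current rates. Edges
between class pairs never observed to exchange are held at the lower bound
and flagged unidentifiable. `fit_rates_global()` maximizes the summed
likelihood of several records over one shared rate set — the "global
rates" workflow — and `rates_vs_voltage()` tabulates fitted edges across
holding potentials.

## Model discrimination by EMD and MDS

`amplitude_histogram()` builds all-points amplitude densities on a shared
grid (100 bins, -0.2 to 1.2 of the full-open current; the axis is
normalized by the full-open current so distances are dimensionless and
comparable across voltages). `emd_1d()` is the 1-D optimal-transport
distance in its closed form — the integrated absolute difference of the
CDFs — and `mds_embed()` is classical (Torgerson) scaling, deterministic
up to rotation.

`model_discrimination_report()` ranks candidate models by their mean EMD to
a set of experimental histograms. Models can be supplied once (one
simulation compared to every record) or per record (rates derived per
channel, mirroring comparison against per-recording fitted rates).
By default the model histograms are built by mixing *simulated
class-conditional* amplitude shapes with the model's *exact stationary*
class occupancies. This is a variance-reduced estimator of the stationary
amplitude distribution: the occupancy weights carry no sampling noise, so
at desk-scale simulation lengths the ranking reflects amplitude structure
(merged hump vs. distinct sublevels, flicker noise) rather than which
simulation happened to draw an active or quiet window. Plain empirical
histograms of stationarity-converged simulations are available via
`weighting = "empirical"`.

The `region` argument restricts the comparison to an amplitude window,
renormalizing both distributions there. `region = c(0.15, 0.95)` compares
the *sublevel-structure* region only — between the closed and full-open
peaks — which is where a merged substate (one broad hump), explicit
sublevels (distinct peaks) and fast flicker (shifted, noise-broadened
levels) actually differ. This mirrors comparing substate-conditional
amplitude distributions, and it matters statistically: when the competitor
schemes are occupancy-matched to the reference (as the lumped and couplet
analogues are by construction), the full all-points distributions differ by
only ~0.01 EMD, below the sampling noise of any desk-scale record, whereas
the sublevel-region distances separate the schemes decisively.

```{r discrimination, eval = FALSE}
spec <- cohort_spec(n_channels = 1, voltages = 30, record_duration = 60,
                    base_model = "M1_reduced", seed = 1)
co <- generate_cohort(spec)
models <- list(M1_reduced = co$model,
               M2 = lapply(co$model, as_merged_substate),
               fast_gating = lapply(co$model, as_fast_gating))
model_discrimination_report(co$trace, models, voltage = 30, chunk = 60,
                            region = c(0.15, 0.95), seed = 2)
```

`as_merged_substate()` lumps a model by stationary class-level flux rates
(preserving occupancies and transition frequencies exactly), and
`as_fast_gating()` substitutes flicker couplets for explicit sublevels —
the two competitor constructions used throughout.

## Voltage-level analyses

`boltzmann_fit()` fits Po(V) = Po_max / (1 + exp((dG + zFV)/RT)) by
nonlinear least squares (V in volts and dG in J/mol internally; T defaults
to 295.15 K). A negative effective gating charge z means Po rises with
depolarization. Initialization takes Po_max from the largest observed Po
and dG, z from a logit-linear fit; voltage-insensitive data are returned as
a flagged flat fit with z = 0 rather than an error. `current_partition()`
splits each record's mean current into full-open and substate
contributions, aggregates by voltage, and extrapolates the substate
percentage to 0 mV by linear regression over voltages up to +20 mV (the
window is a documented parameter; direct measurement at 0 mV is impossible
because amplitudes vanish).

## The synthetic cohort generator

`generate_cohort()` emulates the statistical structure of a bilayer study
cohort: per channel, one log-normal multiplier per edge (default SD 0.3,
which places inter-channel amplitude-histogram EMDs in the 0.3–0.4 band
on the normalized axis, matching reported inter-experiment distances);
~11% of channels gate voltage-independently at boosted activity; the rest
scale their activating closed-state transitions up ~10x from -30 mV to a
plateau above +20 mV and slow the full-open-to-substate return ~3x between
+10 and +20 mV — exponential forms in V, a modelling choice since
per-voltage fits constrain only the endpoints. Records pass through the
standard acquisition chain; ground-truth paths and per-record models are
returned alongside the traces.

What the generator does *not* emulate: baseline drift, capacitive
transients, 50/60 Hz interference, multi-channel superposition, and any
ligand (Ca2+, pH) modulation. Passing tests on this testbed demonstrates
the estimators and the discrimination logic, not robustness to those
artifacts.

## Numerical choices and problem sizes

* Stationary distributions: least-squares null space of the augmented
  t(Q); irreducibility checked by strong connectivity.
* Matrix exponentials: eigendecomposition when the eigenbasis is well
  conditioned, otherwise scaling-and-squaring; the dead-time integral uses
  the augmented-exponential identity and needs no inverse.
* SKM convergence: < 0.1% of samples changing assignment, at most 20
  iterations; non-convergence returns the best iterate, flagged.
* Dwell-mixture optimization: BFGS with analytic gradients, reltol 1e-14;
  degenerate fits flagged at < 5% tau separation or < 1e-4 area.
* MIL: L-BFGS-B, factr 1e7, restarted while the objective improves by
  more than 0.5; likelihood floored (never -Inf) so line searches retain
  gradient information.
* Default analysis settings mirror the acquisition conditions: 100 kHz
  digitization, 1 kHz Gaussian filter, 10 kHz analysis rate, 0.6 ms dead
  time.

The test suite exercises the pipeline at deliberately desk-scale problem
sizes — couplet simulations of a few seconds to tens of seconds,
rate-recovery records of ~10^4 events fit globally across three records,
discrimination cohorts of 120 s records with 60 s model simulations, 50
seeded replicates for component-count selection — chosen so that each
statistical claim is testable at the precision asserted.

## Known limitations

* The first-order missed-event correction leaves a few-percent downward
  bias on rates coupled to heavily truncated sublevel dwells; exact
  Hawkes–Jalali–Colquhoun asymptotics would remove it.
* Within-aggregate rate constants are identifiable only when their
  timescales separate; the presets are designed accordingly, and fits of
  poorly separated schemes should be interpreted via their flagged
  standard errors.
* EMD values depend on the histogram normalization and grid; only
  comparisons on the shared default grid are meaningful, and absolute
  distances are not comparable to analyses using other conventions.
* The fast-gating couplet mapping fixes the fast closing rate alpha; the
  apparent-level match degrades if alpha approaches the filter corner
  frequency (the tests require alpha + beta at least 20x the 1 kHz
  cutoff).
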