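---
title: "Modelling sequence-dependent DNA breathing with dnabreathe"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling sequence-dependent DNA breathing with dnabreathe}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dnabreathe)
```

## The model

Double-stranded DNA at physiological temperature is not statically
zipped: individual base pairs transiently separate and re-close
("breathing"), and runs of simultaneously open pairs form transient
*bubbles*. Promoters — in particular the region around the transcription
start site (TSS) — are thought to exploit this: a promoter whose TSS
region breathes strongly and coherently presents single-stranded DNA to
the transcription machinery more readily than one whose dynamics is weak
and evenly spread.

`dnabreathe` models this with the extended Peyrard–Bishop–Dauxois (EPBD)
mesoscopic Hamiltonian. Each base pair *n* carries a single transverse
coordinate $y_n$ (Å), the stretch of its hydrogen bonds away from the
closed minimum. The potential energy is

$$
U(y) = \sum_n D_n\left(e^{-a_n y_n} - 1\right)^2
     + \sum_{n\ge 2} \frac{k_n}{2}
       \left(1 + \rho\, e^{-\beta (y_n + y_{n-1})}\right)
       (y_n - y_{n-1})^2 .
$$

The Morse on-site term models the hydrogen bonds: two-bond A:T pairs get
a shallow, wide well ($D_{AT} = 0.05$ eV, $a_{AT} = 4.2$ Å$^{-1}$ by
default), three-bond G:C pairs a deeper, narrower one
($D_{GC} = 0.075$ eV, $a_{GC} = 6.9$ Å$^{-1}$). The anharmonic stacking
term couples neighbours: near the closed state its stiffness is
$k(1+\rho)$, and it relaxes to $k$ once either neighbour opens. This
entropic softening is what makes opening cooperative — a site next to an
already-open site is much easier to open — and it is what produces
multi-base-pair bubbles rather than independent single-site flickers.
The "extended" aspect of the model is that $k$ may be made dinucleotide-
step dependent via a 16-entry table (`epbd_parameters(k_stack = ...)`);
the package ships with the homogeneous default
$k = 0.025$ eV/Å$^2$, $\rho = 2$, $\beta = 0.35$ Å$^{-1}$ because no
single published step table is canonical, and users supply their own
through the parameter config.

All defaults live in `epbd_parameters()` and a YAML round-trip
(`read_epbd_config()` / `write_epbd_config()`); nothing is hard-coded in
the kernels, and every results file echoes the effective parameters.

## Dynamics

Thermal motion is generated by Langevin dynamics at fixed temperature
(300 K default): Newtonian forces from the exact analytic gradient of
$U$, friction $-\gamma m \dot y$, and matched Gaussian noise. The
integrator is the BAOAB splitting — a stochastic velocity-Verlet-class
scheme whose velocity substep is the exact Ornstein–Uhlenbeck update, so
the fluctuation–dissipation balance holds at any time step, and whose
$\gamma = 0, T = 0$ limit is plain velocity Verlet. That limit gives a
free correctness probe: the test suite integrates a displaced chain for
$10^5$ steps and requires total-energy drift below $10^{-6}$ eV.

Internally the code works in Å, amu and eV; the derived time unit is
$t_0 = \mathrm{Å}\sqrt{\mathrm{amu/eV}} \approx 10.18$ fs, and the
default step of 10 fs is about one internal unit. A stability guard
($\mathrm{d}t \cdot a_{max}\sqrt{k_B T/m} < 0.1$) rejects steps too
large for the stiffest Morse wall.

**Friction.** The package default is $\gamma = 5$ ps$^{-1}$, of the
order of the Morse well frequency. Two reasons. First, thermostat
physics: a chain started from the closed state absorbs latent heat as it
partially melts toward equilibrium; at very weak coupling
(e.g. 0.05 ps$^{-1}$) the thermostat resupplies that heat so slowly that
the kinetic temperature reads several percent low for hundreds of
picoseconds. At 5 ps$^{-1}$ kinetic energy equilibrates within a
fraction of a picosecond. Second, sampling: base-pair opening is a
barrier crossing, and its rate is maximal for friction near the well
frequency (the Kramers turnover); far below it, openings are
energy-diffusion limited and short trajectories contain almost no
events. Equilibrium averages are friction-independent, so this choice
affects only efficiency and the (dynamical) lifetime scale, which lands
in the sub-picosecond-to-picosecond range conventional for breathing
studies. $\gamma$ remains a plain config field.

**Walls.** Reflecting walls at $y = -2$ Å and $y = +20$ Å bound the
coordinate. The Morse plateau makes the unbounded single-site partition
function divergent; with a shared wall, the Langevin sampler and the
independent quadrature oracle
(`equilibrium_opening_probability_oracle()`) integrate over exactly the
same domain, so the Boltzmann-marginal check is an equality test (within
Monte-Carlo error), not an approximation. The single-site validation in
the test suite uses $\gamma = 0.5$ ps$^{-1}$ and multi-nanosecond runs:
with heavy damping a single site needs $\sim L^2 \gamma m / k_B T$
(over a nanosecond) to diffuse across the 22 Å box, so a lighter
friction is the appropriate choice for that particular diagnostic.

**Seeding.** One master seed per run; each replica's child seed is the
i-th draw from the master-seeded stream, so results depend only on
(master seed, replica index), not on execution order. Child seeds are
drawn rather than arithmetically spaced: linearly spaced `set.seed`
values produced measurably correlated streams (replica-mean dispersion
about twice the independent-replica prediction), which drawing removes.

## Bubble detection and profiles

A bubble of length $L$ at start position $p$ (its 5'-most base pair) is
open in a frame iff $y_j \ge$ threshold for all $j \in [p, p+L-1]$.
`detect_bubbles()` extracts maximal runs of consecutive open frames as
half-open `[birth, death)` events; events touching either trajectory
boundary are flagged censored, since their true lifetime is only
bounded below. `lifetime_profile()` pools events across replicas into
occupancy, mean-lifetime and event-count arrays over
(threshold × length × TSS-relative position), with:

* default thresholds $\{0.5, 1.0, 1.5, 2.1\}$ Å and lengths up to 20 bp,
  spanning the range conventional in the breathing literature;
* censored events dropped from lifetime means by default (they only
  lower-bound the true lifetime and would bias short-run means
  downward; a `"keep"` policy exists for sensitivity checks); occupancy
  is unaffected by censoring;
* a 5-bp margin excluded at each chain end, so the open-boundary choice
  (terminal pairs have one stacking partner) cannot colour reported
  profiles;
* positions numbered TSS-relative with the TSS at +1 and no position 0,
  the standard promoter convention.

Occupancy is exactly subset-monotone — a stricter threshold or a longer
bubble is satisfied on a subset of frames — and the test suite asserts
this on computed profiles, not just on paper.

## TSS-window summaries and the contrast verdict

`summarize_tss_window()` reduces one threshold slice to window versus
background statistics; the *focus ratio* (window mean occupancy over
background mean occupancy) measures how concentrated breathing is at the
TSS. Window lifetime is the event-count-weighted mean over window cells;
of the estimator variants examined (unweighted cell means,
length-weighted, occupancy-weighted), the event-weighted mean had the
best signal-to-noise for contrasting promoters and is the default.
`compare_profiles()` declares "A more TSS-focused than B" iff A wins on
both the focus ratio and the window mean lifetime. The verdict is a
deliberate conjunction of inequalities, not a statistical test —
the underlying claim is qualitative, and uncertainty is conveyed by
repeating the comparison across master seeds.

The generic default window is ±50 bp around the TSS. For the shipped
60-bp synthetic designs the examples and tests use ±10 bp: on a 60-bp
chain a ±50 window would swallow every retained position, leaving no
background and an undefined focus ratio.

## Synthetic data: what it emulates and what it does not

Real promoter sequences for the profile contrast this package
operationalizes are not redistributable here, so `synthetic_data`
generators stand in for every input class:

* `make_sequence()` draws promoter-like sequences (60–300 bp) with a
  set background GC fraction and composition blocks. The canonical pair
  is `focused_design()` — 60 bp, GC-rich (0.8) background, a 10-bp
  AT-only block centered on the mid-sequence TSS — versus
  `flat_design()`, the same background with no block. The AT block is a
  caricature of the AT-rich TSS-proximal elements of breathing-active
  promoters; GC 0.8 keeps the background comparatively quiet.
* `make_planted_trajectory()` builds trajectories with rectangular
  plateau events on known cells and baseline noise clipped below the
  detection thresholds, so detector acceptance is exact rather than
  statistical.
* `make_ct_table()` inverts the comparative-CT formula to produce Ct
  tables with known fold changes and optional Gaussian cycle noise.

Passing tests on these designs show that the machinery — simulation,
detection, aggregation, comparison — behaves correctly and that an
AT-block promoter stand-in is reliably more TSS-focused in *occupancy*
than a flat one at small scale. They do not show that any real
promoter pair differs, and the synthetic sequences carry no motif
content, no flanking genomic context, and far shorter length than real
promoter windows.

At the small test scale (50 ps production × 20 replicas) the
*occupancy* contrast between the two designs is robust in every seed we
measured, while the *lifetime* half of the conjunctive verdict is
marginal: above a 1.0 Å threshold both A:T and G:C excursions evolve on
their Morse plateaus, so individual event durations are nearly
base-independent, and the residual cooperative-lifetime effect (~5%) is
comparable to its estimator's standard error at that scale. The full
verdict therefore fires in roughly three quarters to nine tenths of
seeds at test scale rather than always; at publication scale (1 ns ×
100 replicas) the event counts are two orders of magnitude larger.

## Expression arithmetic

`ddct_fold_change()` implements the comparative-CT method: arithmetic
means on the cycle scale, $\Delta Ct$ per condition against a reference
gene (default TBP), fold $= 2^{-\Delta\Delta Ct}$ with ideal doubling
per cycle (no Pfaffl-type efficiency correction, which the comparative
method does not use). `classify_regulation()` applies a strict
"more than two-fold" rule: fold > 2 is up, fold < 0.5 is down, exactly
two-fold is unchanged. `pulse_peak_power()` validates pulsed-source
metadata: a 1 µJ, 35 fs pulse has peak power $\approx 2.9\times10^7$ W
(30 MW at one significant figure), and at 1 kHz repetition its 1 mW
average power is consistent with a declared 1 mW/cm² density over a
~1 cm² spot.

## Numerical choices and problem sizes

* Quadrature: `stats::integrate` with relative tolerance $10^{-8}$,
  split at $y = 0$ so the adaptive rule resolves the narrow well.
* Gradient validation: central differences with step $10^{-6}$ Å;
  agreement required to $10^{-6}$ eV/Å per component on random states.
* Test problem sizes: 50 ps × 20 replicas for profile-level checks,
  1.6 ns aggregate for the thermostat check, 2 + 4 ns single-site runs
  for the Boltzmann marginal; chosen so the whole suite runs in a few
  minutes while each statistical assertion keeps a comfortable margin.
* Degenerate inputs: empty FASTA yields an empty list; ambiguity codes
  are rejected, never imputed (the Hamiltonian has no parameters for
  them); zero-length windows and empty Ct tables are errors, not NAs.

## Known limitations

* One coordinate per base pair: no helicoidal twist, no strand
  asymmetry, no sequence-dependent Morse parameters beyond the AT/GC
  classes, no solvent or ion model.
* Lifetimes are dynamical quantities and depend on the friction
  coefficient; only their relative comparison between sequences run
  under identical settings is meaningful.
* The reflecting wall at 20 Å, needed for a finite partition function,
  makes the fully-denatured state artificially recurrent for a single
  uncoupled site; coupled chains at 300 K are far from that regime.
* No claim connecting breathing profiles to measured transcription is
  made or tested by this package.
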