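---
title: "Mechanistic simulation of fast and slow NHEJ repair"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mechanistic simulation of fast and slow NHEJ repair}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nhejsim)
```

# The model

`nhejsim` simulates the repair of radiation-induced DNA double-strand breaks
(DSBs) by non-homologous end joining (NHEJ) in G0/G1 cells, where homologous
recombination is unavailable and repair proceeds with biphasic kinetics: a
fast, resection-independent component and a slow, resection-dependent
component that requires CtIP/EXO1-driven end resection and the nuclease
Artemis.

Each DSB is split into two independent *ends*, agents that

* diffuse sub-diffusively through a spherical nucleus (10 um diameter by
  default), and
* progress through a protein-loading state graph by stochastic races.

Every state transition has a mean time $\tau$; an actual transition time is
drawn from $\mathrm{Exp}(1/\tau)$. When a state has several outgoing
transitions, one time is drawn per candidate and the shortest wins. Pathway
choice is therefore an emergent property of the time constants, not a
programmed branching ratio.

## The state graph

```
naked --(race: Ku recruitment 1.1 s | inhibition 0.85 s)--> ku_bound | inhibited
inhibited --(release 3.8 s)--> naked            (the end re-enters the race)
ku_bound --(race: DNA-PKcs 1.2 s | CtIP 7.0 s)--> pk_fast | ku_ctip
ku_ctip --(EXO1 1.2 s)--> ku_ctip_exo1 --> resected_awaiting_pk
resected_awaiting_pk --(resection + Artemis:DNA-PKcs 500 s)--> pk_artemis_slow
pk_artemis_slow --(blunt 60 s model A / 400 s model B)--> blunt_slow
```

The Ku inhibition/release cycle deserves a comment: after release the end
re-enters the recruitment/inhibition race and may be inhibited again. A
single-pass race would put Ku on more than 90% of ends within a few seconds;
repeated cycling is what stretches the loading curve so that roughly 80% of
ends carry Ku at 10 s, which is the behaviour recruitment experiments show.

`ku_ctip_exo1 -> resected_awaiting_pk` is a zero-time bookkeeping step: once
EXO1 has loaded, the end is by definition in the resection process awaiting
DNA-PKcs:Artemis. The single 500 s constant deliberately lumps resection
completion and Artemis:DNA-PKcs recruitment into one transition — there is no
recruitment-level data that would let the two be separated, so inventing two
constants would only pretend to more knowledge than exists. The branch
commitment (fast at `pk_fast`, slow at `ku_ctip`) is permanent.

## Synapsis, two topologies

Two ends within the capture radius (25 nm) can form a synaptic complex,
which then moves as one object. A formed complex races *stabilisation*
(mean 250 s) against *dissociation* (mean 400 s); a stable complex ligates
after an exponential ligation time, gated on both ends being ligatable and
lesion-free. Additional base lesions are removed at 300 s each, additional
single-strand breaks at 900 s each; these clocks run on fast-branch ends
inside a complex. Slow-branch ends are blunt — resection has already removed
their extra lesions.

The two topologies differ in how the branches meet:

| feature                                   | model A ("parallel") | model B ("entwined") |
|-------------------------------------------|----------------------|----------------------|
| cross-branch synapsis                     | no                   | yes                  |
| synapsis-eligible slow states             | `blunt_slow` only    | from EXO1 loading    |
| dissociation of slow-slow complexes       | no                   | yes                  |
| ligation time fast / slow (s)             | 1200 / 8000          | 3000 / 3000          |
| bluntification time (s)                   | 60                   | 400                  |

In model B a resecting end (EXO1 loaded onward) can already join a complex —
including with a fast-branch partner — and its Artemis end-processing then
completes inside the complex before ligation. This is the mechanistic heart
of the "entwined" hypothesis, and it is also what lets model B avoid the
mismatch problem: in model A an end that committed to the slow branch can
never join its fast-committed partner, and since the two ends of one break
choose independently (probability $2 p q \approx 0.25$ of a mismatch at the
ungated slow fraction $p \approx 0.146$), a substantial plateau of unrepaired
DSBs accumulates. That contrast — model A residual at 24 h at least that of
model B — is asserted by the test suite on identical damage inputs.

## Knockouts and chromatin gating

Deficient cell lines are modelled by editing single links:

* **Artemis deficiency** deletes the 500 s step; every end that recruits CtIP
  reaches `resected_awaiting_pk` and stalls there. Because its fast-committed
  partner is then orphaned, the *emergent* residual fraction is the
  site-level probability that at least one end resects, $2p - p^2 \approx
  0.27$, not the per-end fraction $p \approx 0.146$: with a 25 nm capture
  radius in a 10 um nucleus, two orphaned fast ends from different breaks
  essentially never meet, so no cross-origin rescue occurs. The test suite
  computes both numbers and records the comparison.
* **CtIP inhibition** deletes the `ku_bound -> ku_ctip` edge. On top of the
  Artemis knockout it removes the stalling path entirely and restores
  wild-type-like repair (the rescue experiment).
* **XLF deficiency** shortens the synapsis dissociation constant to 11 s, so
  a formed complex dissociates before stabilising with probability
  $(1/11)/(1/11 + 1/250) \approx 0.958$ — repair still completes, but much
  more slowly.

Chromatin gating (off by default) models compaction-dependent pathway
choice: CtIP recruitment is blocked in euchromatin, and each heterochromatic
end is DNA-PKcs-eligible with probability 0.4, rolled once per end when Ku
loads. The roll is exclusive — an eligible end takes the fast branch, an
ineligible end recruits CtIP. With 25% heterochromatin this gives a
resection-dependent share of $0.25 \times 0.6 = 0.15$ exactly; letting the
eligible ends still race CtIP would instead give
$0.25(0.6 + 0.4 \times 0.146) \approx 0.165$, which is not the 15% the gated
variant is designed to produce. The exclusive reading is consistent with the
idea that an abundance of infiltrating DNA-PKcs outcompetes CtIP wherever it
gains access.

# Damage generators

The photon generator draws the number of DSBs per cell from
$\mathrm{Poisson}(25 \cdot \mathrm{dose})$ and places them uniformly in the
nucleus — the dose homogeneity of photon exposures justifies uniformity.
Strand-break level utilities follow the same conventions: the induction
probability ramps linearly from 0 at 5 eV to 1 at 37.5 eV of deposited
energy, and opposite-strand breaks within 10 bp cluster into a DSB site
(greedy nearest-pair, deterministic after sorting; verified against a
brute-force oracle).

Per-end lesion complexity is not constrained by recruitment or repair data
at the level this package models, so each end carries
$\mathrm{Poisson}(0.5)$ extra base lesions and $\mathrm{Poisson}(0.3)$ extra
single-strand breaks by default. This gives the lesion-cleaning transitions
work to do without dominating the kinetics; both means are configurable.

The track-like generator is explicitly a stand-in for full track-structure
transport: DSBs are placed along straight chords with a per-track linear
density (default $0.05 \cdot \mathrm{LET}$ per um) and per-end complexity
increasing with LET. It produces the clustered spatial structure needed for
LET sweeps of residual damage, nothing more. Neither generator emulates
chromosome territories, base-pair-resolution geometry, or correlated
multi-site clusters along secondary electrons — conclusions drawn from
passing tests are about the repair mechanics, not about damage-spectrum
realism.

A minimal text dialect of the Standard DNA Damage (SDD) format round-trips
damage sets (`writeSDD()`/`readSDD()`): a `Key, value;` header terminated by
`***`, then one comma-separated record per site. Unknown header keys warn
and are skipped; malformed records are an error naming the line, never a
silent skip.

# Motion

Ends and complexes move by a continuous-time random walk: instantaneous
isotropic Gaussian jumps (per-axis variance $2 D \tau_J$) separated by
heavy-tailed trapping times with $P(W > w) = (1 + w/s)^{-\alpha}$. With
$\alpha < 1$ the mean trap time is infinite and the ensemble MSD grows as
$t^\alpha$ — genuine sub-diffusion, reproduced by the test suite with
$\hat\alpha = 0.5 \pm 0.15$.

Defaults and their reasoning:

* `jumpDiffusionCoefficient` $D = 6 \times 10^{10}$ nm$^2$/s — the
  model-level diffusion coefficient the repair results are fitted with.
* `waitTimeExponent` $\alpha = 0.5$.
* `jumpDuration` $\tau_J = 4 \times 10^{-10}$ s and `waitTimeScale`
  $s = 5$ s. The jump cadence and duration are free parameters of the CTRW
  implementation; they were chosen so that (i) a single jump moves an end
  ~12 nm (3-D RMS), below the 25 nm capture radius, so that partner ends
  separate gradually rather than teleporting apart, and (ii) the cumulative
  24 h per-end displacement is in the hundreds of nanometres, the scale
  live-imaging studies report for DSB ends. Under these defaults the
  wild-type entwined model repairs ~95-99% of 2 Gy photon damage by 24 h,
  i.e. the kinetics regime the model family is built to reproduce. Large
  jumps (e.g. $\tau_J = 10^{-5}$ s, ~2 um per jump) scatter co-located
  partner ends across the nucleus before Ku can load, after which the 25 nm
  capture radius is never satisfied again and essentially nothing ligates.

The nuclear boundary is reflective (radial fold-back at the surface),
conserving the object count and keeping ends available for synapsis. A
synaptic complex is one mobile object: both member ends share its position
exactly.

## Motion/reaction coupling

Reactions are event-driven (sampled transition times absorb into the tick
that covers them); motion and synapsis checks run on a tick grid: 0.1 s
ticks until 100 s, then geometric growth by 1.05 per tick capped at 10 s.
Late-stage event times (hundreds to thousands of seconds) far exceed jump
times, so the growing tick loses nothing. The schedule is exposed in
`simulationConfig()` and the suite asserts that halving every tick changes
the 24 h mean residual by less than one DSB. Degenerate cases are handled
deterministically: exactly tied race times take the lowest transition index
(a measure-zero event), pairing among more than two mutually close ends is
greedy by ascending distance, and a freshly dissociated pair sits out one
tick before it may re-form (an arbitrary refractory period; at the 0.1-10 s
tick scale it is far shorter than any reaction time constant).

# Observables

* `repairCurve()` / `countUnrepaired()`: unrepaired DSB equivalents, i.e.
  (ends not in a ligated complex)/2 — cross-origin (misrepair-candidate)
  ligations count as repaired, and are tallied separately in the complex
  table. They are permitted by the 25 nm rule but not validated against
  translocation data.
* `recruitmentCurve()`: a protein is "loaded" from first entry into its
  loading state until the state boundary that removes it — Ku from
  `ku_bound` until ligation; DNA-PKcs and Artemis from `pk_fast` *or*
  `pk_artemis_slow` (both branches) until ligation; CtIP from `ku_ctip` and
  EXO1 from EXO1 loading until the 500 s step completes. Counts are
  normalised per repeat to the initial DSB number, averaged, then rescaled
  to the curve maximum within 30 s (60 s for Artemis), matching how laser
  recruitment data are normalised. Values may exceed 1 after the window;
  that is expected for slow contributions and tested. One consequence worth
  noting: Artemis shares DNA-PKcs's state intervals, yet its curve reaches
  80% later (~16 s rather than ~11 s) purely because of the wider
  normalisation window.
* `reducedChiSquare()`: $\chi^2/\mathrm{DF} = \sum_i ((s(t_i) - y_i)/
  \sigma_i)^2 / N$ with the simulated curve linearly interpolated at the
  experimental times, $\sigma_i$ the experimental SEMs and DF the number of
  points — nothing is fitted at comparison time, so no parameter count is
  subtracted. `aggregateChiSquare()` reports the unweighted mean plus the
  best and worst single-series statistics.
* `residualVsLet()`: ordinary least squares through (LET, mean residual at
  the horizon).

# Reproducibility and problem sizes

Repeat $k$ of a simulation is seeded with `masterSeed + k`; a master seed
reproduces event logs exactly, and generator seeds reproduce damage files
byte-for-byte. The test suite runs the full-scale reference condition (2 Gy
photons, 70 repeats, 24 h horizon, entwined model) once, and sizes the
remaining checks to their statistical needs: 10,000 generator seeds for the
Poisson yield, 100,000 sites for chromatin labelling, ~7,000 ends for
recruitment values, ~20,000 ends for the gated branching fraction, and
10-24 repeats for knockout and robustness contrasts, with closed-form race
probabilities checked at $n = 10^5$ draws against $3\sigma$ binomial bands.

# Known limitations

* No track-structure physics, chromosome geometry or Hi-C-informed
  chromatin: chromatin is a Bernoulli label at a configurable fraction
  (0.48 or 0.25 in practice).
* No explicit ATM signalling, no MRE11/EXO1 distinction, no explicit
  XLF/XRCC4/LigIV molecules (XLF deficiency acts through the dissociation
  constant only).
* Ku loading is irreversible; whether Ku can unload is not represented.
* Whether the 40% heterochromatin DNA-PKcs chance should be per end or per
  site is undetermined biologically; it is applied per end, consistent with
  end independence.
* Misrepair is tallied, not validated; foci-counting optics, low-dose
  hypersensitivity and visco-elastic bounded motion are out of scope.
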