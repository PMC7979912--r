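---
title: "Models and methods: nucleation control in crisscross polymerization"
author: "crisscross package"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods: nucleation control in crisscross polymerization}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(crisscross)
```

## The problem

Seed-controlled self-assembly requires two properties that are usually in
tension: a large kinetic barrier to spontaneous (seed-independent)
nucleation, and fast, effectively irreversible growth once a seed is
present.  Conventional DNA tile systems bind only nearest neighbours, so
their half coordination number `n` (the number of bonds a monomer must make
to be stably attached under near-reversible conditions) is small — 2 for
square tiles (ST), 3 for hexagonal tiles (HT) — and their nucleation
barrier collapses as growth is driven harder.  Crisscross slats (CS) are
elongated monomers carrying a linear array of `2n` weak binding sites, each
specific to one conjugate site on one of `2n` perpendicular slats; `n` can
be made arbitrarily large, which sustains the barrier under irreversible
conditions.  This package implements the complete computational side of
that comparison: the kTAM barrier analysis, a stochastic seeded-growth
model with analytic solution and fitting, gel-densitometry quantification
of spontaneous nucleation, an ssDNA slat sequence designer, and synthetic
data generators that exercise every stage.

## kTAM free energies and the energy unit

Assemblies are scored with the kinetic Tile Assembly Model form

$$G(A) = N\,g_{mc} - B\,g_{se},$$

where `N` is the monomer count, `B` the bond count, `g_mc` the per-monomer
concentration cost, and `g_se` the per-bond energy.  All energies are in
*decades* (log10 units), so a barrier difference of `d` decades means a
`10^d`-fold difference in expected spontaneous-nucleation rate.  The
irreversibility parameter is `eps = n * g_se - g_mc`: the log10
attachment:detachment ratio of an `n`-bond attachment (`eps = 2` is 100:1
growth:shrinkage).

The absolute offset comes from the kTAM standard state.  We take
`g_mc = log10(c0 / c)` with `c0 = 20` M, the effective standard
concentration conventional in kTAM simulation; at the benchmark 1 uM
monomer concentration this gives `g_mc = 7.301` decades.  With that single
choice, the continuum saddle-point barriers below reproduce all four
benchmark barriers of the tile-versus-slat comparison at `eps = 2` —
10.8 (ST), 13.9 (HT), 34.4 (CS `n = 6`) and 45.8 (CS `n = 8`) decades — to
the printed precision, with no per-architecture adjustment.  This is the
calibration shipped as the default.

## Landscapes: discrete search and continuum saddles

`criticalNucleus()` computes the minimal-barrier landscape: among all
attachment orderings over connected assemblies, the ordering that
minimizes the maximum of `G`.  Because attachments add one monomer at a
time, every pathway visits exactly one state per size, and the minimax
pathway is found exactly by a best-first (Dijkstra-style) search over
canonicalized states with priority equal to the maximum `G` so far
(`minimaxBarrier()`).  An independent oracle, `enumerateBarriers()`,
enumerates every connected state layer by layer with no priority queue;
the two agree exactly on all three architectures for assemblies up to 8
monomers (this is asserted in the test suite).

For CS the exact search is only needed as a cross-check: the minimal
pathway is the alternating *staircase* in which each added slat crosses
every perpendicular slat already present, giving
`B(N) = floor(N^2/4)` for `N <= 2n`.  Since no bipartite crossing state
can exceed that bond count, the staircase is provably optimal for this
free-energy form, and `method = "staircase"` evaluates it in closed form
at any size.  Past the complete `n x n` junction every addition makes `n`
bonds, so `dG = -eps` per slat and growth is downhill.

`analyticBarrier()` gives the continuum (real-valued cluster size) saddle
points used for the calibrated comparison:

* CS: maximize `2x g_mc - x^2 g_se` over staircase depth `x`, giving
  barrier `n g_mc^2 / (g_mc + eps)` at `2 n g_mc / (g_mc + eps)` monomers;
* ST: rectangle saddle `g_se^2 / eps` on the square lattice, capped by the
  tube-wrap pathway `(m + 1)(g_mc - g_se)` for circumference `m` when the
  saddle outgrows the tube;
* HT: hexagonal (Wulff-shape) cluster saddle on the triangular lattice,
  `-eps(3s^2 - 3s + 1) + (6s - 3) g_se` at side `s = g_se/eps + 1/2`,
  similarly capped by the ring pathway.

The integer-lattice minimax and the continuum saddle differ by a fraction
of a decade (e.g. 34.7 versus 34.4 for CS `n = 6` at `eps = 2`); the
continuum values are the ones quoted for the calibrated comparison, while
all ordering, monotonicity and slope properties are asserted on both.
Where the critical nucleus composition is constant, the discrete landscape
obeys `d(barrier)/d(eps) = -B*/n` exactly, because
`G = N g_mc - B (g_mc + eps)/n`.

Two conventions are worth stating.  First, at the near-reversible plateau
(`eps -> 0`) the profile maximum is attained by both the `(n, n-1)` and
the complete `(n, n)` junction; ties within numerical tolerance are
reported as the completed junction (critical size `2n`, e.g. 12 monomers
for `n = 6`), matching the physical picture of the critical nucleus as
`n` y-slats plus `n` x-slats.  Second, a profile still rising at
`max_size` means the barrier is not bracketed, and the search refuses to
report one rather than returning a lower bound.

`matchArchitectures()` constructs the equal-footing comparison: given a
reference system, it chooses the integer tube circumference whose
reversible-limit barrier — `(m+1) g_mc / 2` for ST rings,
`(2m+1) g_mc / 3` for HT — comes closest, then rescales the monomer cost
(equivalently, shifts the concentration, by well under half a decade) so
the match is exact.  Matching CS `n = 6` yields `m = 11` for ST with no
rescaling at all, and `m = 9` for HT.  The seed is modeled purely
energetically (`landscapeWithSeed()`): a pre-formed edge presenting `2n`
handle sites, so each nucleator capture and each subsequent addition makes
`n` bonds and the seeded profile descends by `eps` per slat — the seed
pre-pays the barrier.

## The stochastic growth model

Seeded ribbons elongate by slat addition.  `simulateRibbons()` evolves
each ribbon end as a continuous-time Markov process: a growing state
elongating at velocity `v` (nm/s), a stalled state (rates `k_stall`,
`k_resume`), and an absorbing terminated state entered at rate `k_term`
from either state (termination is phenomenological; mechanistically it is
attributed to incorporation of truncated slats at the growth front, which
this model does not resolve).  Ribbons start in the stationary
growing/stalled mixture, which makes the analytic mean exact at all
times rather than only asymptotically:

$$\langle L(t)\rangle = \frac{v_{\mathrm{eff}}}{k_{\mathrm{term}}}
  \left(1 - e^{-k_{\mathrm{term}} t}\right),\qquad
  v_{\mathrm{eff}} = v\,\frac{k_{\mathrm{resume}}}
  {k_{\mathrm{resume}} + k_{\mathrm{stall}}},$$

reducing to `v_eff * t` as `k_term -> 0`.  This saturating form produces
the non-linear length-versus-time profiles characteristic of fast growth
with termination.  The reported standard deviation comes from the
termination-dominated reduced model `L = v_eff * min(t, T)` with `T`
exponential; stall-state fluctuations perturb the spread only at second
order for the parameter regimes of interest.  A discrete
per-slat-addition stall variant was considered and not implemented: at
1.5 nm per slat and micron-scale lengths the continuous-time limit is
indistinguishable at TEM measurement precision.

`fitGrowthModel()` fits `(v_eff, k_term)` by weighted least squares on
per-timepoint mean lengths (weights: inverse squared standard error of
the mean), with the parameters log-transformed for positivity, using
Levenberg-Marquardt.  Spontaneous nucleation `J` is only identifiable
from unseeded counts and is therefore not part of the seeded fit.
Confidence intervals are bootstrap-based (lengths resampled within each
timepoint, 200 resamples by default).  The default interval is
*bootstrap-normal* (estimate plus/minus z times the bootstrap standard
error): for these near-symmetric estimators it is well calibrated
(~95% empirical coverage in the package's own recovery study), whereas
raw percentile intervals at a few hundred resamples undercover slightly;
`ci_type = "percentile"` remains available.

Polydispersity is summarized as `PDI = mean(L^2)/mean(L)^2`
(weight-average over number-average).  Monodisperse populations give 1,
exponential length distributions give 2; seeded growth with synchronized
starts is substantially narrower than spontaneous nucleation with
staggered (Poisson) starts, and the simulated seeded PDI at paper-like
parameters falls inside the empirically reported 1.07-1.53 band.
`rateConstantFromVelocity()` converts velocity to a second-order on-rate
via `k_on = v_eff / (delta * c_slat)` with `delta = 1.5` nm per slat.

## Gel quantification and censoring

`unseededRateFromGel()` implements the two-step-protocol quantification:
ribbon concentration in an unseeded lane equals the background-subtracted
intensity ratio to a seeded control lane of known seed concentration
(single-point calibration through the control; intensities normalized per
loaded volume; seed conversion taken as complete by default), and the
nucleation rate follows as concentration over the nucleation-phase
duration.  The chain of unit conversions
(`slatsPerRibbon()`, `ribbonsToMolar()`, `ribbonMass()`,
`nucleationRateEndpoint()`) reproduces the worked detection-limit
arithmetic: a 5 um ribbon carries ~3300 slats at 1.5 nm/slat; half a
million such ribbons are ~200 fM in 4 uL and ~60 pg of DNA, at the
~65 pg/lane agarose detection floor; 200 fM accumulated over 100 h is a
rate of ~0.6 aM/s.  Any lane whose implied concentration falls below the
floor (default 200 fM) is *censored*: it never yields a point estimate,
only an upper bound at the floor.  Reporting rounds to 2 significant
figures for counts while retaining full precision internally.

## Sequence design

A slat core is a linear array of `2n` half-turn binding domains of 5 or
6 nt; four consecutive domains span two helical turns and must sum to
`2 * bp_per_turn` nucleotides (21 nt at 10.5 bp/turn, with the repeating
5,5,5,6 pattern; 22 nt at 11.0 bp/turn, alternating 5,6).  Phase-shifting
the 10.5 pattern gives loosely coiled ribbons and underwinding to
11.0 bp/turn tightly coiled ones (`twistReport()`); 3-4 nt sticky ends
close coils into tubes (`decorateBlueprint()`).

`buildBlueprint()` constructs the crossing map: x-slat `i` crosses
y-slats `i .. i + 2n - 1`, pairing x-domain `d = j - i` with y-domain
`2n - 1 - d`, a bijection at the role level for every symmetry mode
(`full`: `2n` distinct x and y roles; `n_pairs`: `n`; `half_n_pairs`:
`n/2`, even `n` only).  x-slats never cross over between helices;
y-slats cross over every half turn (recorded as a threading annotation).
The `2n` nucleating y-slats are chimeras: the ribbon-proximal half
repeats the corresponding periodic y role, the other half presents unique
seed handles.  The seed interface itself (origami scaffold/staple
routing) is out of scope and abstracted as those handle domains.

Orthogonal sequences come from a GF(4) single-parity-check code: all
words whose base values (A=0, C=1, G=2, T=3) sum to a fixed residue mod 4
differ pairwise at two or more positions, so the default Hamming floor of
2 holds *by construction* after filtering to the GC window (0.30-0.70)
and homopolymer cap (4).  The filtered 5-mer pool holds 160 words and the
6-mer pool 800, enough for a v6 full design (156 distinct 5-nt domains);
seed handles draw from a disjoint coset.  Stricter floors fall back to
greedy rejection sampling and fail loudly when infeasible.  x-domains are
derived as exact reverse complements of their conjugate y-domains, which
preserves within-class pairwise distances.

Self-structure is screened with a hairpin proxy — the longest pair of
non-overlapping subsequences that are exact reverse complements, found by
dynamic programming and cross-checked against an exhaustive search in the
tests — in place of a full thermodynamic fold.  Assembled slats with
stems of 8 nt or more are regenerated; stems shorter than that melt far
below the 46-56 C growth temperatures, and demanding the absence of even
6-nt stems across all ~36 slats of a v6 design is combinatorially
infeasible for random sequence pools.  A hook for an external folding
engine can be added by replacing `scoreSelfStructure()` in the screen.
Base-stacking polarity (`stackingPolarity()`) uses the nicked-duplex
dinucleotide stacking free energies of Protozanova et al. (2004) and
requires the mean junction stack to be more stabilizing along y than
along x, matching the design intent of the characterized slat sets;
`assignSequences()` regenerates until the polarity holds.

`designGenomeNucleators()` folds a 190-nt window of an arbitrary ssDNA
genome with six nuc-x-slats whose genome-binding domains tile the window
in near-equal consecutive blocks (32,32,32,32,31,31 nt) as exact reverse
complements — the equal-block partition is a package choice where the
exact per-domain split is not dictated by the design rules — with the
remaining domains presenting v6 y-slat handles.  Exports
(`exportSequences()`) are deterministic: FASTA via Biostrings plus a
column-major 96-well plate CSV.

## Synthetic data: what it emulates and what it does not

`synthLengthDataset()` emulates TEM length measurements: independent
filament cohorts at each timepoint (as in repeated grid preparation),
per-time sample sizes drawn from 130-168, multiplicative lognormal
measurement noise (default sd 5%, a placeholder for the unreported
tracing error of the segmented-line protocol, exposed as a parameter)
and a 50 nm minimum measurable length.  `synthGelDataset()` emulates
background-subtracted lane intensities, linear in ribbon concentration
with additive Gaussian noise (default 2%) and a 200 fM-equivalent floor.
Scenario presets parameterize a fast 50 C-like regime (micron-scale mean
lengths within hours: `v = 0.25` nm/s, `k_term = 1/12 h^-1`), a slow
40 C-like regime several-fold slower, and an unseeded-nucleation gel
scenario at 1 aM/s probed over 100 h.

What passing the recovery tests shows is that the estimation machinery is
unbiased and calibrated *under the generating model*: real TEM data add
tracing and selection biases (entangled ribbons are excluded by the
measurement protocol), real gels add background-subtraction and loading
variability, and none of that is represented here.  The generators share
the analysis models' structural assumptions, so these tests validate the
inference, not the models' adequacy for any particular experiment.

## Numerical choices and limitations

Problem sizes used in the shipped tests: exact-search oracle equivalence
to 8 monomers on CS `n = 2` and circumference-4 ST/HT tubes; Monte-Carlo
agreement at 10^4 ribbons with a 3-standard-error criterion; recovery
studies at 150 ribbons x 5 timepoints x 100 replicates with 200 bootstrap
resamples.  Seeds are fixed throughout; all generators are reproducible
byte-for-byte under a fixed seed.  Tie-breaking in the searches is
lexicographic on canonical state labels; canonical keys quotient out
translation and tube rotation but not reflection (which costs only
duplicate work, never correctness).

Known limitations: the kTAM analysis is thermodynamic-kinetic bookkeeping
on `G(A)`, not a full rate-equation or kinetic Monte-Carlo simulation;
temperature enters only through condition labels, never as a rate model;
the stall/termination kinetics are phenomenological; tube closure
mechanics and origami seed structure are represented only as annotations
and energetic boundary conditions.
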