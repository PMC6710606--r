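---
title: "The RGC model: averaging fragment efficiencies, the subtractive average, and fragment rescue"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The RGC model: averaging fragment efficiencies, the subtractive average, and fragment rescue}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rgcscreen)
```

## The problem

Fragment-based drug design screens small fragments (typically 8–16 heavy
atoms) against the sub-pockets of a target and elaborates the hits into a
drug-sized compound, most directly by linking one fragment per pocket.
The standard triage metric is ligand efficiency, LE = ΔG/N: the binding
free energy per heavy atom. Screens conventionally keep only fragments
whose individual LE clears a cutoff (0.3 kcal mol⁻¹ HA⁻¹ is the common
threshold), which silently assumes each fragment must carry its own
weight. The relative group contribution (RGC) view instead judges the
*combination*: the efficiency of the assembled molecule is estimated from
its parts, so a below-cutoff fragment survives whenever its partners are
efficient enough to lift the whole — the fragment "rescue" effect.

## Model and assumptions

Three assumptions underpin the machinery implemented here:

1. The efficiency of a multi-fragment molecule can be estimated from its
   component fragments' LE values, by a weighted root-mean-square (WRMS)
   average whose weights reflect fragment size; a plain arithmetic mean
   is the equal-size special case and is exact there.
2. Each fragment's LE is measured from its own binding to its own pocket,
   independently of the others (no cooperativity).
3. Linking is, to first order, additive: the molecule's ΔG is the sum of
   fragment ΔG values and its N the sum of fragment N values.

Under these, `leApparentArithmetic()` and `leApparentWrms()` compute the
apparent total LE (LETapp), and the subtractive average `leDelta*()`
inverts them: given a target LETapp, `x` pockets, and `a` fragments
already fixed, it returns the common LE the remaining `x − a` fragments
must reach. Useful identities, all enforced by the test suite at relative
tolerance 1e-10: a single-fragment molecule has its fragment's LE; with
nothing known the requirement is the target itself; with one unknown left
it is exactly that fragment's required LE; and the requirement is
strictly decreasing in each known fragment's LE — the quantitative form
of rescue.

### The WRMS subtractive average

The arithmetic LE_δ follows from solving the mean for the unknown block.
The WRMS counterpart is derived here as the unique value consistent with
re-insertion: writing W_tot = Σ w_j + (x−a)·w_δ, the value

LE_δ = sqrt( (LETapp²·W_tot − Σ LE_j²·w_j) / ((x−a)·w_δ) )

is the one for which substituting (x−a) copies of (LE_δ, w_δ) alongside
the known pairs back into the WRMS reproduces LETapp. A naive
subtractive form that omits the total-weight normalisation and the
square on LE_δ fails both boundary identities above (a = 0 and
x − a = 1), so the round-trip-consistent form is the one implemented;
the identities double as its arbitration tests, and
`wrmsDeltaByRootFinder` in the test helpers re-derives it numerically
with `uniroot` on every random slate.

When the known fragments alone already push the WRMS past the target
(the bracket goes negative), no real LE_δ exists: `leDeltaWrms()`
returns `NA` as a first-class infeasibility signal rather than raising,
because the screening layer consumes it as "unreachable" during pruning.
Negativity within 1e-12 of zero (relative) is clamped to zero as
rounding.

### Sign conventions

ΔG is stored signed, ΔG = RT·ln(K_d), negative for binders — the
standard thermodynamic convention — and all efficiency metrics default
to the magnitude convention (|ΔG|/N, the familiar positive scale), with
`"signed"` available everywhere. The WRMS refuses mixed-sign input
outright: squaring would silently erase the distinction between binders
and non-binders. Non-binders (ΔG ≥ 0) are accepted by the metrics layer
but flagged, and excluded by the screen unless `allowNonbinders = TRUE`.
Temperature defaults to 298.15 K with R = 1.987e-3 kcal mol⁻¹ K⁻¹; both
are overridable via `thermoParams()`. K_d inputs are accepted in M, nM
or µM and converted at parse time; energies are kcal/mol throughout.

## The screen

`screenFragments()` enumerates one fragment per pocket and accepts
exactly the combinations whose LETapp (in the configured mode) reaches
the cutoff; the cutoff is interpreted as the target LETapp of the final
compound, and every pocket must be filled. A depth-first search prunes
with admissible bounds only, so the accepted set is provably identical
to exhaustive enumeration (and is tested to be, against a brute-force
oracle):

* arithmetic mode — a partial choice is cut when even the per-pocket
  maxima of the remaining pockets cannot lift the mean to the cutoff;
* WRMS mode — the bound takes the largest achievable LE²·w per remaining
  pocket over the smallest achievable weight, which can only overstate
  the achievable WRMS.

Bounds are relaxed by 1e-9 before cutting so a branch sitting on the
acceptance boundary is never lost to rounding; acceptance itself is the
exact inequality `LETapp >= cutoff - tolerance` with `tolerance = 0` by
default (the knob exists for users who want an explicit band around the
requirement). Accepted combinations are reported sorted by LETapp
descending, ties broken lexicographically by fragment id — the ordering
is a reporting convention, nothing in the model depends on it — and
`maxCombinationsReported` truncates the report only after
classification, which always uses the full accepted set.

Each library fragment (keyed `pocket:fragment`, since the same id may
recur in different pockets as a distinct entity) is classified
`selected` (own LE at or above the cutoff, member of an accepted
combination), `rescued` (below the cutoff yet a member) or `rejected`
(member of none). `classicSelection()` provides the conventional
per-fragment triage for comparison, and `requiredLeForRemaining()`
exposes the running LE_δ during an interactive design, with an explicit
feasibility flag against what the library can still supply.

## Weight policy

The WRMS weights "depend on size", but no unique functional form is
forced by the model. The default is linear, w_i = N_i — the simplest
choice under which a fragment's influence on the estimate scales with
the atoms it contributes, and under which equal-size fragments reduce
the WRMS to an unweighted RMS. `defaultWeights()` also offers `sqrt_n`
(damped size dependence) and `equal`. The ideal weight w_δ of the
unknown block defaults, in the screen, to the mean heavy-atom count of
the candidate fragments in the unfilled pockets; callers can supply an
atom budget instead.

## The synthetic generator

`generateLibrary()` draws fragment LE values per pocket from a normal
distribution truncated at zero (truncation keeps the magnitude
convention coherent; the untruncated spread is the stated `leSd`) and
back-computes ΔG = −LE·N. Defaults describe a realistic campaign:
two pockets (the linking case), eight candidates per pocket, LE centred
at 0.3 kcal mol⁻¹ HA⁻¹ with spread 0.1, fragments of 8–16 heavy atoms.
`linkFragments()` assembles the "true" thermodynamics of a linked
molecule as

ΔG_T = Σ ΔG_i + ΔG_rigid + ΔG_binding + ΔG_strain + ε,  N_T = Σ N_i + N_linker,

with ε ~ N(0, noiseSd) drawn once per molecule: non-additivity is
modelled as a whole-molecule phenomenon, not per-fragment measurement
error. With all corrections, linker atoms and noise at zero, linking is
perfectly additive, and with equal fragment sizes the arithmetic LETapp
equals the directly computed LE_T = |ΔG_T|/N_T identically — the regime
where the model's approximation is an equality, asserted exactly in the
tests. `compareLeT()` simulates molecules, records both predictions
against LE_T with absolute and relative deviations, and summarises mean
absolute deviation and Spearman rank correlation per mode.

What the generator does **not** emulate — and therefore what passing
tests do not demonstrate about real data: binding hot spots and
super-additive linking, fragment pose changes upon elaboration,
measurement error structure of real assays, correlated affinities
within a pocket, and any real chemistry in the linker. The generator's
role is to make the model's internal claims (identities, dominance
relations, degradation under non-additivity) assertable, not to stand in
for experimental validation.

## Numerical choices

* Identity and round-trip assertions: relative tolerance 1e-10; the
  closed-form-vs-root-finder cross-check runs at 1e-8 (`uniroot` at
  tol 1e-13).
* Kd/ΔG round trip: relative 1e-12 across 1e-15–1e3 M.
* Pruning slack 1e-9 (conservative only — never changes the accepted
  set, only how much is pruned).
* Degenerate inputs: `leSd = 0` collapses a pocket to its mean exactly;
  `ΔN = 0` is a hard error for group efficiency; empty pockets and
  all-non-binder libraries are hard errors for the screen; cutoff 0 is
  permitted and accepts everything.
* Determinism: all generation runs under a locally scoped seed (the
  global RNG stream is restored), and molecule sampling runs under an
  offset of the config seed so it does not replay the library stream;
  identical configs give bitwise-identical libraries and byte-identical
  reports.

## Problem sizes

The test suite verifies the algebraic identities on 1,000 random
parameterisations per identity and both averaging modes; round trips on
400 random slates (x ≤ 6); screen-vs-enumeration equivalence on 200
random libraries of up to 4 pockets × 6 fragments; and the simulation
claims on 200 molecules per noise level over a seed-fixed ladder
(noise sd 0, 0.5, 1, 2 kcal/mol). These sizes were chosen to exercise
the combinatorics thoroughly while keeping the full suite around a
minute on one CPU.

## Known limitations

The model inherits every limitation of LE itself: a single scalar per
fragment, agnostic to lipophilicity, selectivity and synthesisability.
Cooperativity between pockets is assumed away (assumption 2), so targets
with strong hot-spot behaviour will defeat the estimate in either
direction. The WRMS weight form is a modelling choice, not a derived
quantity. And the rescue logic optimises reaching a target LETapp — it
says nothing about whether the rescued combination is chemically
linkable; the linker corrections in the simulator are placeholders for
exactly the effects the screen ignores.
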