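---
title: "Impedance-based transdermal-rate screening: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Impedance-based transdermal-rate screening: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mnscreen)
```

## The problem

Metallic sheet microneedle arrays — parallel steel sheets, each carrying a
row of sub-millimetre needle tips — are used for transdermal sensing and
drug delivery. Their performance depends on how many tips actually pierce
the stratum corneum, but penetration is unreliable and cannot be observed
directly in use. Because an unpenetrated tip rests on the highly resistive
stratum corneum while a penetrated tip contacts conductive tissue, the
electrical impedance between two sheets carries information about how many
tips on each sheet failed to penetrate. `mnscreen` implements the full
chain from a forward electrical model of the array-in-skin system, through
exhaustive penetration-state sweeps that calibrate current intervals, to
the combinatorial decoders that turn a handful of pairwise current
measurements into per-sheet unpenetrated-tip counts and a transdermal
rate.

## Forward model

### Geometry and materials

The skin is simplified to two layers: a 100 um stratum corneum at
0.0005 S/m over a 1.8 mm conductive layer at 0.2 S/m that pools the viable
epidermis and dermis (the capacitive, frequency-dependent behaviour of
real skin is deliberately outside the DC model). The array —
`array_geometry()` — defaults to 100 um thick sheets, 200 um wide and
800 um long needles at 800 um tip and sheet pitch, inserted 600 um. The
skin block extends laterally so the array footprint occupies one-ninth of
the skin area (a 3x margin per axis), which pushes the insulating outer
boundary far enough out that fringe effects do not dominate pairwise
currents.

### Contact impedance and the penetration flag

Each tip `XY` carries a binary flag: 1 = unpenetrated, 0 = penetrated.
The metal/tissue interface is a thin contact layer, 20 um thick, whose
conductivity mixes the two skin layers by the flag:

    sigma_contact = (1 - XY) * sigma_dermis + XY * sigma_sc

so an unpenetrated tip sees the stratum corneum (0.0005 S/m) and a
penetrated tip the dermis (0.2 S/m). This single boundary parameter is
what lets an exhaustive state sweep reuse one geometry: flipping flags
never changes the mesh.

### Discretisation and solve

`discretize()` voxelises the block into cubes (50 um default; 100 um is
the coarse setting used for sweeps — it is the coarsest size that still
resolves the sheet thickness, the stratum corneum and the insertion depth
exactly). Needle-occupied voxels are carved out; every face between a
carved voxel and remaining skin becomes a contact face tagged with its
(sheet, tip). The steady conduction equation `div(sigma grad phi) = 0` is
discretised by the standard 7-point finite volume with harmonic-mean face
conductances; each contact face couples its skin voxel to the owning
sheet's potential node with conductance
`sigma_contact * A_face / t_contact`.

The sheets themselves are not meshed. With a metal/dermis conductivity
ratio of 5e7 a sheet is an equipotential body to any accuracy that
matters, so each sheet is a single potential unknown: the driven sheet is
fixed at 1 V, the ground sheet at 0 V, and non-tested sheets are floating
nodes constrained to zero net current (an `"absent"` mode removes them
instead; whether the reference characterisation kept them present is
unknowable, so both are supported and floating is the default). This
avoids a 5e7 conductivity contrast inside the linear system and keeps it
well conditioned.

The system is symmetric positive definite and solved by a sparse
supernodal Cholesky factorisation (CHOLMOD via the Matrix package);
within a sweep the symbolic factorisation is reused across all states,
since only contact conductances change. The solve is deterministic; a
relative residual above `relative_tolerance` (default 1e-8) raises an
error, and in practice direct solves sit at machine precision, as does
source/ground current balance (tested at 1e-6). `validate_homogeneous_slab()`
checks the machinery against the closed form `G = sigma A / L` on a
homogeneous block with plate electrodes, where the half-cell Dirichlet
coupling makes the discretisation exact up to solver round-off.

Two deliberate simplifications: needles are rectangular prisms (the real
tip taper is not in the model — the reference mesh is unknown and contact
area differences are second order for the orderings the package asserts),
and the 200 um of needle above the skin carries no current (air is
insulating). For the same reason **absolute currents are not comparable
to the packaged tables**; only orderings, contrasts and interval
structure are asserted anywhere in the package.

### What the forward model reproduces

The test suite verifies, at the 100 um sweep resolution, the qualitative
structure the decoding method depends on: per-state mean currents
strictly decrease along the state ranking; every record of the 3x3 sweep
falls inside its own state's computed interval; the distance-2 pair
(A-C) gives uniformly weaker currents than the adjacent pair; flipping
any single tip to unpenetrated never increases the current; and swapping
the two sheets' patterns changes the current only at the 1e-3 level
(the A-B midplane is not an exact symmetry plane of the finite block, so
the unordered-state premise holds up to fringe effects, orders of
magnitude below the within-state spread). A fully unpenetrated pair is
suppressed by a large factor that is bounded above by the
stratum-corneum/dermis conductivity ratio (400): the dermis spreading
resistance is common to both circuits, so the full-circuit contrast is a
few tens, not the naive 400.

## States, ranking and calibration

A pairwise test only reveals the unordered pair of unpenetrated-tip
counts — the *transdermal state*, canonicalised low-high (`"0-2"`), with
the pooled nonconductive class `"n+"` when a sheet is fully unpenetrated
(the current then collapses and the state-current correspondence is
lost). The dominant factor in the current is the larger count, so states
rank by ascending `(high, low)`; `substate_count()` gives the number of
position-specific assignments (events) realising a state over an ordered
pair, `2*C(n,low)*C(n,high)` or `C(n,low)^2` on the diagonal.

`interval_boundaries()` turns per-state mean currents into a calibration
table by the midpoint rule: the boundary between adjacent ranked states
is the mean of their means; the first interval is half-open above and
the nonconductive class closes at 0. Ties in adjacent means are refused
as degenerate rather than broken arbitrarily.

The packaged tables (`packaged_table()`) transcribe the printed
characterisation of the reference 3x3, 4x4 and 6x6 devices verbatim, one
column set per sheet-pair distance. The print is internally inconsistent
in places (the 3x3 distance-1 column's intervals 5 and 6 overlap over
171-177 uA and three printed lengths contradict their own bounds; the
4x4 distance-2 column prints an upper bound of 394 where its neighbours
imply 294). The transcription deliberately preserves these;
`check_table_consistency()` surfaces exactly the affected rows, and the
decoder resolves overlap hits toward the higher-current interval while
flagging the pair as ambiguous. The 6x6 state grouping (which states
share an interval) is likewise taken from the print rather than
re-derived, since it encodes the reference model's current clustering.

## Decoding

`lookup_state()` maps a current into its interval (half-open
`[lower, upper)`). The **exact method** then works on states:
`exact_decode_three()` implements the three-sheet branch logic — if the
two A-C counts are equal then A = C and the A-B state yields B,
otherwise B is the count common to the A-B and B-C states — with
multiset matching (a duplicated count can be used only once), and
`exact_extend()` chains each further sheet from one adjacent-pair state.
Physically impossible inputs raise an inconsistency error naming the
offending pair, and any nonconductive pair fails loudly rather than
guessing. The method is gated to one-to-one tables (3x3, 4x4): grouped
6x6 tables are a usage error. An exhaustive oracle in the test suite
decodes every conductive truth vector for 3- and 4-sheet arrays.

The **fuzzy method** needs only per-pair maxima (`N_max_s`), which
grouped tables still provide (an interval mixing maxima — the 6x6
interval 4 holds one max-2 state among three max-3 states — contributes
its event-count mode). `fuzzy_max_med()` recovers the maximum and median
of three sheet counts from the three pairwise maxima (verified against a
sort oracle on all `{0..6}^3` triples), and the totals follow the two
estimation formulas `N = N_MAX + 1.5 * N_MED` per sheet triple and
`N = 1.5 * sum(pairwise maxima)` for disjoint pairs — the 0.5 factor is
the guess for each unknown minimum. The schemes leave 1/3 and 1/2 of the
per-sheet information undetermined respectively, reported as
`unknown_rate`. Arrays whose sheet count is divisible by 3 (or even)
apply the printed formula per disjoint triple (pair) and sum; other
sheet counts are not given a formula and are refused. The transdermal
rate is `1 - N / total_tips`, matching the convention that 9 of 9
penetrated tips is 100% and 3 of 9 is 33.3%.

## Synthetic fixtures

`generate_fixture()` emulates a bench measurement: a per-tip
Bernoulli(`p`) truth, then one current per sheet pair — the
representative in-interval current of the pair's true state under the
calibration table for its distance (interval midpoint; the half-open
first interval uses its boundary plus half the median closed-interval
width), or the forward-solved current — plus Gaussian noise of chosen
standard deviation. All randomness flows through the single seed, so a
fixture is bit-exact reproducible. What the generator does *not*
emulate: electrode polarisation, drift, AC effects, or any correlation
between tips — so passing end-to-end tests demonstrate the logic and
the calibration plumbing, not robustness to real measurement artefacts
beyond additive noise. The noise-robustness test checks only the
monotone claim (quarter-interval noise breaks no more decodes than
full-interval noise), which is the property a practitioner relies on.

## Problem sizes and defaults

The test suite runs the exhaustive 3x3 sweep (64 combinations per pair,
both the adjacent and the distance-2 pair) at the coarse 100 um
resolution, computed once and shared across tests; single-solve checks
use the same grid. The 50 um default is for interactive single solves.
Fixture-based statistics use 25-40 seeded replicates. These sizes are
the package's choices for a thorough-but-snappy default run; nothing in
the science changes at finer resolution except slower, slightly larger
currents.

## Known limitations

* Absolute currents depend on the unknown reference mesh and tip shape;
  use computed calibrations end-to-end (sweep -> calibrate -> decode) or
  the packaged tables end-to-end, never mixed.
* The DC model ignores skin capacitance and frequency dependence.
* The exact method requires every tested pair conductive; one fully
  unpenetrated sheet forces the fuzzy method (or no estimate).
* Printed-table quirks are preserved, so lookups in the 171-177 uA
  region of the 3x3 distance-1 table are inherently ambiguous and are
  flagged as such.
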