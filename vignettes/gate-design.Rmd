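---
title: "Designing and verifying DNA-interface logic gates"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Designing and verifying DNA-interface logic gates}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dnatransformr)
```

## The model

A gate is a core particle carrying an output marker (a terminal biotin
whose steric accessibility constitutes output = 1), shielded by
nanoparticles attached through DNA bridges. Each bridge is a chain

    core receptor — staple₁ — … — staple_{m−1} — shield ligand

whose junctions are severable by toehold-mediated strand displacement
(TMSD): an input oligonucleotide binds an unpaired toehold on the
core-proximal strand of a junction and branch-migrates through the
adjacent duplex, evicting the strand on the shield side. The package
models this at the *domain level*: strands are sequences with explicit
paired spans, and a displacement step is atomic — toehold binding plus
complete branch migration through the input's migration span. A displaced
incumbent leaves the junction entirely once the junction's residual
paired region is no longer thermodynamically committed (below, *hold
threshold*); otherwise the partially displaced state persists, which is
exactly what makes cooperative AND junctions work.

Two readout conventions share one mechanism. *Shield bridges* realize the
positive (monotone) part of a Boolean function: the shield departs when
any junction of its chain is severed. *Marker bridges* realize negation:
the marker-bearing strand is pre-hybridized to a core receptor and leaves
the particle when its release condition fires, so the marker is present
only while the condition is false. The particle binds its target iff
every shield has departed *and* at least one marker strand remains — all
shields co-located on one particle block the whole surface, which is why
assemblies compose conjunctively while marker strands compose
disjunctively.

### What is compilable on a single particle

Writing each bridge condition in disjunctive normal form (one OR term per
junction; a multi-input term becomes one cooperatively partitioned
junction), the architecture realizes exactly

$$ f \;=\; \Big(\bigwedge_i G_i\Big) \wedge \Big(\bigvee_j \lnot H_j\Big), $$

where every $G_i$ (shield) and $H_j$ (marker release) is a positive gate
of fan-in ≤ 4 on one staple chain, and every input drives exactly one
invasion site (reusing an input at two sites would require duplicated
complementary receptors, i.e. built-in cross-talk). Functions outside
this class — the smallest is `x OR NOT y` — require mixtures of particle
species, which trade the all-in-one stoichiometry for exactly the
balancing problems the single-particle design avoids; the compiler
rejects them with an explicit error rather than silently splitting the
design. `AND(NOT a, NOT b)` is rewritten as `NOT(OR(a, b))` (one marker
released by either input), so NOR-type logic stays in reach.

### Signal mapping

The analog output is a two-point linear map, normalized like the gate
panels it imitates: `signal_min` (default 0.04) for the fully assembled
state, `signal_max` (default 1.0) when all shields are gone and all
markers present, interpolating linearly in the fraction of exposed marker
strands for partially released marker sets. The Boolean decision level is
the geometric mean `sqrt(signal_max_state * signal_min_state)` — with the
defaults, 0.2 — reflecting the semi-logarithmic dose–response reasoning
behind that threshold choice. Because inputs never appear on both the
shield and the marker side of one gate, the no-shield-input combination
always exposes every marker, so the observed maximum is `signal_max` and
the threshold is robust: with up to four marker terms the weakest true
state (one of four markers exposed, signal 0.28) still clears 0.2 by a
40% margin.

## Thermodynamic layer

Duplex free energies are nearest-neighbor sums over stacked steps with
duplex initiation and terminal-A·T penalties, using the unified DNA
ΔH°/ΔS° table shipped as a TSV (`inst/extdata/nn_unified_dna.tsv`), with

* temperature entering through ΔG°(T) = ΔH° − TΔS° (defaults: 310.15 K
  for gate operation, 298.15 K via `assembly_params()` for assembly,
  matching the high-salt room-temperature assembly conditions);
* monovalent salt as the standard entropic correction
  ΔS°[Na⁺] = ΔS°[1 M] + 0.368·N·ln[Na⁺] per stack (defaults 0.15 M
  operation, 0.5 M assembly), which is monotone: more salt never
  destabilizes.

The hairpin screen is deliberately restricted: contiguous stems of ≥ 2
Watson–Crick pairs closed by terminal loops of ≥ 3 nt, stem energy from
the duplex model, an additive tabulated loop penalty (treated as purely
entropic for temperature rescaling, Jacobson–Stockmayer extrapolated past
30 nt), and exhaustive enumeration over all stem/loop placements — exact
within this class and fast at oligo scale (n ≤ 80). Bulges, internal
loops, multiloops and pseudoknots are out of scope: the screens this
layer serves are hairpin-floor constraints, not structure prediction. A
sequence admitting no hairpin at all returns `Inf` ("no structure"),
which passes any floor.

AMFE, the per-base-pair stability score of an interface complex, is the
complex ΔG divided by its number of complementary pairs. Since AMFE is
negative, "larger AMFE" is ambiguous; the package treats *magnitude* as
the stability direction and leaves the signed value available, since both
conventions appear in practice.

## Tunable parameters

| Parameter | Default | Units | Rationale |
|---|---|---|---|
| toehold length | 5 | nt | in the regime where TMSD rate is strongly toehold-dependent but not saturated; configurable 3–8 |
| `dg_hold` | −8.0 | kcal/mol | residual-duplex commitment threshold, near the stability of 5–6 mixed pairs at 37 °C; ties count as stable |
| AND margin | 2.0 | kcal/mol | every proper input subset of a cooperative junction must leave a residual at least this far below `dg_hold`; violations are a compile error naming the offending segment lengths |
| cross-run cap (input design) | 3 | nt | "lack of complementarity" operationalized as: no contiguous complementary run of 4+ nt |
| cross-run cap (compiled-object screens) | 4 | nt | sub-toehold for the default 5-nt toehold: a tolerated run cannot nucleate displacement |
| GC window | 0.40–0.60 | fraction | keeps nearest-neighbor energies moderate; standard oligo hygiene |
| homopolymer cap | 4 | nt | synthesis and screening hygiene |
| hairpin floor, inputs | 0 | kcal/mol | inputs must be free of any negative-free-energy hairpin |
| hairpin floor, output receptor | −2.0 | kcal/mol | the separate 30-nt output receptor only needs to avoid *pronounced* structure |
| `signal_min`, `signal_max` | 0.04, 1.0 | a.u. | normalized two-point readout; threshold √(1.0·0.04) = 0.2 |

The two screening caps differ on purpose. The printed input-design rule
is strict (runs < 4 nt) and is kept for `design_input_pair()`. Species
generated *by the compiler* (shield ligands, the separate output
receptor) are screened against every input **and** every input's reverse
complement — the latter because each input's full complement is displayed
on the particle as a receptor, so identity runs between two inputs become
physical cross-hybridization sites. That doubles the number of
simultaneous constraints; the compiler therefore screens its generated
species at the sub-toehold cap of 4 nt, which is the same criterion
`validate_design()` applies and is still displacement-incompetent under
the default toehold.

## Sequence derivation inside the compiler

For a junction with term inputs $x_1 \ldots x_p$, the upstream strand
carries one block `[migration][toehold]` per input, equal to that input's
reverse complement, so the invader pairs its full length contiguously;
the downstream strand pairs the migration segments only, leaving every
toehold open in the assembled state (a structural invariant that
`validate_design()` re-checks). Multi-segment derived strands are joined
with 3-nt spacers; the spacer triple is chosen deterministically from a
small candidate set to suppress complementary runs that would otherwise
span segment boundaries — a failure mode no per-segment constraint can
see. Single-junction shield bridges end in a static staple/ligand duplex
whose ligand is generated by rejection sampling; the *assembled* staple
(arm + spacer + static arm) is what gets screened, and the ligand is
resampled until it passes. The staple's receptor-binding arm is by
construction an identity copy of a cognate-input segment, so cognate
inputs are excluded from the staple's *complementarity* screen (identity
is not complementarity); the bounded self-complementarity of designed
inputs caps those runs instead.

## The fixture generator

`generate_fixtures()` is the package's synthetic-data module: it stands
in for the wet system's specific oligonucleotides, which live in
supplementary tables and are not transcribed here. It regenerates
constraint-equivalent inputs — InA at 17 nt and InB at 28 nt (the
dual-gate input sizes), hairpin-free above the 0 kcal/mol floor, mutually
non-complementary below the run cap, plus two further inputs (20 and
22 nt, chosen as typical short-oligo sizes) for the four-input gate, with
identity runs against earlier inputs capped as receptor-cross-talk
hygiene — and assembles eight gate fixtures: YES and NOT on both inputs,
OR, AND, a four-input single-staple AND, and a composite
`AND(InA, NOT(InB))`. Single-input gates declare the other input as a
bystander, mirroring the non-specific-control lanes of gate panels.
Everything is a pure function of the recorded seed (20240101 for the
committed FASTA, regenerable byte-for-byte).

What passing fixtures do *not* show about real particles: the generator
emulates sequence-level design conditions only. Grafting density,
particle curvature, electrostatics in the crowded interface layer,
nuclease activity and the concentration effects of surface-tethered
duplexes all modulate real switching efficiency and are outside the
domain model, as are absolute optical signal amplitudes — which is why
the simulator works on a normalized two-point scale rather than
predicting absorbance.

## Numerical and procedural choices

* **Equilibrium semantics by default.** Endpoint readouts (incubation
  then washing) justify fixpoint iteration of displacement steps;
  the result is provably order-independent in this model because
  invasion sites are disjoint and toeholds never become blocked, and the
  test suite asserts it over input permutations. Partially displaced
  intermediates persist between input additions — required for AND
  cooperativity and assumed, not measured.
* **Kinetic mode** is optional: a seeded jump process whose effective
  bimolecular rate multiplies tenfold per toehold nucleotide up to a
  6-nt saturation, with a leak floor at zero toehold. Association rates
  in the literature for such systems are of order 10⁶–10⁷ M⁻¹s⁻¹;
  the layer keeps rates configurable rather than fixing absolute values,
  and long-horizon endpoints must (and do) agree with equilibrium mode.
* **Residual energies** of partially displaced junctions are the sum of
  the remaining segments' duplex energies, each scored as an independent
  helix (conservative: each carries its own initiation).
* **Floating point:** energies are doubles; stability and floor
  comparisons use a 1e-9 kcal/mol absolute tolerance; the `<=` tie goes
  to "stable".
* **Determinism:** every stochastic step (sequence sampling, noise,
  kinetics) runs under an explicit Mersenne–Twister seed recorded in the
  artifact; callers' RNG state is restored.
* **Problem sizes in the test suite** (chosen to exercise each property
  at the scale where it is informative): exhaustive hairpin-oracle
  agreement on 1000 random sequences of length ≤ 12; ten hand-summed
  duplex cases; 100 random supported expressions over four inputs
  compiled and simulated against direct Boolean evaluation; 1000 noisy
  replicates for leakage-CV recovery; 200+ seeded kinetic runs checked
  against equilibrium endpoints.

## Known limitations

* The realizable expression class is the single-particle product form
  above; multi-particle mixtures (and hence arbitrary non-monotone
  functions) are intentionally unsupported.
* Branch migration is atomic: no base-level random walk, no partial
  migration intermediates within a segment, no invader competition.
* Hybridization is perfect-match only — no mismatches, bulges or RNA
  parameters; cross-talk is screened by run length, not by energy.
* Cooperative-AND feasibility depends on input composition: a migration
  segment must clear `dg_hold` minus the margin on its own, so short or
  AT-rich inputs are rejected at compile time rather than patched
  silently. The error message reports the offending segment lengths so
  the designer can lengthen inputs or shorten the toehold.
* Geometry (particle sizes, grafting density, multivalent avidity) is
  abstracted into the binary attach/detach state and the linear marker
  interpolation.
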