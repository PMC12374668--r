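# dnatransformr

Design and in-silico verification of Boolean logic gates built on
nanoparticle DNA interfaces.

## The problem

A "particle-disassembly" logic agent is a core particle whose output
moiety (a terminal biotin, the *output marker*) is sterically shielded by a
layer of smaller nanoparticles. Core and shield are held together by DNA
interfaces: a core-anchored *receptor* strand, an optional bridging
*staple* partially complementary to both sides, and a shield-anchored
*ligand* strand. Specific single-stranded DNA inputs disassemble the layer
by toehold-mediated strand displacement (TMSD): an input first binds a
short unpaired *toehold*, then branch-migrates through the adjacent duplex
and evicts the incumbent strand. Which combination of inputs severs the
core–shield bridges encodes a Boolean function — YES, NOT, OR and
cooperative AND gates with up to four inputs on a single staple — and an
exposed marker constitutes output = 1 (e.g. binding a
streptavidin-labelled target).

`dnatransformr` is the design-and-verification side of that workflow, for
researchers building such agents:

* **Thermodynamics** — nearest-neighbor duplex free energies
  ΔG°(T) = ΔH° − TΔS° from a unified parameter table with terminal-AT and
  initiation terms and an entropic monovalent-salt correction
  (ΔS corrected by 0.368·N·ln[Na⁺] cal mol⁻¹ K⁻¹ per stack); a
  restricted hairpin model (contiguous stem ≥ 2 bp, terminal loop ≥ 3 nt,
  tabulated loop penalties) for secondary-structure screens; and the AMFE
  score (complex ΔG divided by its base-pair count).
* **Sequence design** — seeded rejection sampling of oligonucleotides
  under GC-window, homopolymer, hairpin-floor and
  cross-complementarity-run constraints (`generate_oligo()`,
  `design_input_pair()`, `design_staple()`), with machine-checkable
  constraint reports.
* **Gate compilation** — `compile_gate()` turns a Boolean expression over
  named inputs into the full strand set, the domain-level pairing map of
  the assembled state, and one invasion site per input;
  `validate_design()` re-verifies pairing consistency, toehold
  accessibility, hairpin floors, cross-talk and cooperative-junction
  stability margins.
* **TMSD simulation** — `simulate_gate()` and `truth_table()` run
  deterministic, order-independent domain-level displacement to a
  fixpoint and report the gate panel: analog signals per input
  combination, the geometric-mean switching threshold
  √(signal_max·signal_min), the shield ratio (unshielded/shielded
  signal), the leakage CV over false states, and a correctness verdict.
  `kinetic_simulate()` adds a seeded stochastic time course whose
  effective rate grows exponentially with toehold length up to
  saturation.

Results are tibbles throughout; fitted-object style accessors (`tidy()`,
`glance()`, `autoplot()`) cover the report objects, and FASTA/JSON/TSV
readers and writers plus a small CLI (`exec/dtgate`) round out the
toolchain.

## Worked example

```r
library(dnatransformr)

fx   <- generate_fixtures(seed = 20240101)   # deterministic input designs
gate <- compile_fixture(fx, "and_InA_InB")   # AND(InA, InB), N-staple
gate
#> <compiled_gate> AND(InA, InB)  [N_staple, colocalized]
#>   3 strands, 2 junctions, 2 invasion sites, 1 marker strand(s)

tidy(gate)
#> # A tibble: 3 × 5
#>   name  sequence                                      role  anchor modifications
#> 1 i-r1  TAGACCCCATACACTTTACCAACCGCCCTGCCGAGTTTACCTTGT core… core_… "5'-NH2;3'-b…
#> 2 N1    GTAAACTCGGCAGGGCGGTTGGTTTTGTATGGGGTCTATTTAAC… stap… none   ""
#> 3 i-rl1 ACGTAACTGAATTGTGCGTT                          shie… shiel… "5'-SH"

truth_table(gate)
#> <gate_report> AND(InA, InB)
#>   threshold 0.200 (geometric mean), shield ratio 25.0, leakage CV 0.000, CORRECT
#> # A tibble: 4 × 4
#>   combo   signal output expected
#> 1 none      0.04 FALSE  FALSE
#> 2 InA       0.04 FALSE  FALSE
#> 3 InB       0.04 FALSE  FALSE
#> 4 InA+InB   1    TRUE   TRUE
```

Reading the report: the two inputs (17 nt and 28 nt, hairpin-free and
mutually non-complementary by design) each displace only part of the
staple–receptor junction; alone, either leaves a residual duplex stable
enough (below the −8 kcal/mol hold threshold with a 2 kcal/mol margin) to
keep the shield attached, so all three false states sit at the shielded
background (0.04) and the leakage CV is 0. Both inputs together clear the
junction, the shield departs, the marker is exposed (signal 1.0), and the
gate switches at the geometric-mean threshold √(1.0 × 0.04) = 0.2 with a
shield ratio of 25. `validate_design(gate)` re-checks the compiled object
(13 of 13 checks pass). `autoplot(truth_table(gate))` draws the panel.

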