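# Unified DNA nearest-neighbor parameters (1 M NaCl reference, 37 C fit).
# step: 5'->3' dinucleotide on the top strand of a Watson-Crick duplex
#       (all 16 steps listed; complementary steps carry identical values),
#       or one of the special terms `init` (duplex initiation, applied once)
#       and `term_AT` (terminal A-T pair penalty, applied per A/T duplex end).
# dh: enthalpy, kcal/mol.  ds: entropy, cal/(mol K).
step	dh	ds
AA	-7.6	-21.3
TT	-7.6	-21.3
AT	-7.2	-20.4
TA	-7.2	-21.3
CA	-8.5	-22.7
TG	-8.5	-22.7
GT	-8.4	-22.4
AC	-8.4	-22.4
CT	-7.8	-21.0
AG	-7.8	-21.0
GA	-8.2	-22.2
TC	-8.2	-22.2
CG	-10.6	-27.2
GC	-9.8	-24.4
GG	-8.0	-19.9
CC	-8.0	-19.9
init	0.2	-5.7
term_AT	2.2	6.9
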