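# rifadecay nearest-neighbor stacking free energies, table version 1
# Turner-style RNA stacking dG37 (kcal/mol) in DNA alphabet (T stands for U).
# pair5/pair3 columns give the two stacked base pairs read 5'->3' along the
# top (left-arm) strand: pair5 = (top base, bottom base) of the first pair,
# pair3 = the second pair. G:T rows are wobble (G.U) stacks.
pair5	pair3	dg
AT	AT	-0.93
AT	CG	-2.24
AT	GC	-2.08
AT	TA	-1.10
AT	GT	-0.55
AT	TG	-1.36
CG	AT	-2.11
CG	CG	-3.26
CG	GC	-2.36
CG	TA	-2.08
CG	GT	-1.41
CG	TG	-2.11
GC	AT	-2.35
GC	CG	-3.42
GC	GC	-3.26
GC	TA	-2.24
GC	GT	-1.53
GC	TG	-2.51
TA	AT	-1.33
TA	CG	-2.35
TA	GC	-2.11
TA	TA	-0.93
TA	GT	-1.00
TA	TG	-1.27
GT	AT	-1.27
GT	CG	-2.51
GT	GC	-2.11
GT	TA	-1.36
GT	GT	-0.50
GT	TG	1.29
TG	AT	-1.00
TG	CG	-1.53
TG	GC	-1.41
TG	TA	-0.55
TG	GT	0.30
TG	TG	-0.50
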