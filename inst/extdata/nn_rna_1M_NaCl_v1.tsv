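# Watson-Crick RNA/RNA nearest-neighbor parameters, 1 M NaCl, 37 C reference.
# step: 5'XY3' on one strand, paired to its antiparallel complement.
# dh kcal/mol; ds kcal/(K*mol); dg37 kcal/mol. 'init' is duplex initiation,
# 'au_end' the per-terminal A-U pair penalty.
step	dh	ds	dg37
AA	-6.82	-0.0190	-0.93
UU	-6.82	-0.0190	-0.93
AU	-9.38	-0.0267	-1.10
UA	-7.69	-0.0205	-1.33
CU	-10.48	-0.0271	-2.08
AG	-10.48	-0.0271	-2.08
CA	-10.44	-0.0269	-2.11
UG	-10.44	-0.0269	-2.11
GU	-11.40	-0.0295	-2.24
AC	-11.40	-0.0295	-2.24
GA	-12.44	-0.0325	-2.35
UC	-12.44	-0.0325	-2.35
CG	-10.64	-0.0267	-2.36
GG	-13.39	-0.0327	-3.26
CC	-13.39	-0.0327	-3.26
GC	-14.88	-0.0369	-3.42
init	3.61	-0.0015	4.09
au_end	3.72	0.0105	0.45
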