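# Reference doublet free-energy parameters [kcal/mol]
# least-squares fit to 340 experimental perfect-match duplex free energies
AA/TT	-0.838948
AC/TG	-1.394988
AG/TC	-1.323547
AT/TA	-0.375235
CA/GT	-1.406794
CC/GG	-1.698997
CG/GC	-0.967002
GA/CT	-0.938327
GC/CG	-0.711466
TA/AT	-0.144092
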