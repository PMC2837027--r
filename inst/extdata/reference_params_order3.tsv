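# Reference triplet free-energy parameters [kcal/mol]
# least-squares fit to 340 experimental perfect-match duplex free energies
AAA/TTT	-0.844597
AAC/TTG	-1.841904
AAG/TTC	-1.201194
AAT/TTA	-0.991596
ACA/TGT	-1.121939
ACC/TGG	-1.793995
ACG/TGC	-1.615048
ACT/TGA	-0.781693
AGA/TCT	-1.103536
AGC/TCG	-1.528461
AGG/TCC	-1.323278
ATA/TAT	-0.562379
ATC/TAG	-1.157521
ATG/TAC	-1.263601
CAA/GTT	-0.988509
CAC/GTG	-2.088824
CAG/GTC	-1.625284
CCA/GGT	-1.568813
CCC/GGG	-2.396507
CCG/GGC	-1.888906
CGA/GCT	-1.668273
CGC/GCG	-2.195726
CTA/GAT	-0.871636
CTC/GAG	-1.198450
GAA/CTT	-1.317278
GAC/CTG	-1.498999
GCA/CGT	-1.454430
GCC/CGG	-1.973081
GGA/CCT	-1.696158
GTA/CAT	-1.158422
TAA/ATT	-0.519499
TCA/AGT	-1.042342
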