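# TRX dinucleotide flexibility scale: percent of time each phosphate
# linkage class occupies the BII backbone conformation in free solution.
# Strand-symmetric classes; comma-separated member dimers.
class	dimers	score
ApT	AT	0
ApC/GpT	AC,GT	4
ApA/TpT	AA,TT	5
ApG/CpT	AG,CT	9
TpA	TA	13
GpG/CpC	GG,CC	18
GpA/TpC	GA,TC	21
CpA/TpG	CA,TG	25
GpC	GC	25
CpG	CG	43
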