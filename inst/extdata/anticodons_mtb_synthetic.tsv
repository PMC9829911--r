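anticodon	amino_acid	relative_abundance
TGC	A	5.2
GGC	A	4.1
CGC	A	8.8
ACG	R	4.6
CCG	R	3.8
TCT	R	2.2
CCT	R	1.9
GTT	N	4.9
GTC	D	10.0
GCA	C	2.6
TTG	Q	3.4
CTG	Q	4.3
TTC	E	5.6
CTC	E	4.8
TCC	G	5.9
GCC	G	6.4
CCC	G	2.4
GTG	H	3.1
GAT	I	4.4
TAT	I	1.1
CAT	I	1.6
TAA	L	1.0
CAA	L	2.0
TAG	L	2.3
CAG	L	4.0
GAG	L	3.6
TTT	K	3.0
CTT	K	4.2
GAA	F	3.9
TGG	P	4.5
GGG	P	2.1
CGG	P	3.3
TGA	S	3.7
CGA	S	2.8
GCT	S	4.7
GGA	S	2.9
TGT	T	3.5
GGT	T	4.0
CGT	T	2.5
CCA	W	1.8
GTA	Y	2.7
TAC	V	5.0
GAC	V	9.4
CAC	V	3.2
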