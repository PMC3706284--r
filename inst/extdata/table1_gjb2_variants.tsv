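# GJB2 variants identified in the screened cohorts (cases N=658, controls N=462):
# per-variant subject carrier counts and percent frequencies, functional category,
# protein domain and in-silico scores (PolyPhen-2 / SIFT are catalogue metadata).
# Resolution log: the insertion at c.504 is spelled c.504insAAGG (table spelling;
# the running text's "c.504insGCAA" is a typo). Frequencies are half-up 2-dp
# percentages of the carrier count over the group size.
name	aa_change	domain	category	polyphen_score	sift_score	previously_reported	case_carriers	case_freq	control_carriers	control_freq
c.35delG	Frameshift	IC1	pathogenic	NA	NA	TRUE	2	0.30	0	0.00
c.79G>A	Val27Ile	TM1	polymorphism	1.000	0.15	TRUE	135	20.52	65	14.07
c.101T>C	Met34Thr	TM1	polymorphism	0.038	0.12	TRUE	3	0.46	1	0.22
c.109G>A	Val37Ile	TM1	pathogenic	1.000	0.12	TRUE	15	2.28	4	0.87
c.176del16	Frameshift	EC1	pathogenic	NA	NA	TRUE	21	3.19	2	0.43
c.235delC	Frameshift	TM2	pathogenic	NA	NA	TRUE	102	15.50	3	0.65
c.257C>G	Thr86Arg	TM2	pathogenic	1.000	0.00	FALSE	2	0.30	0	0.00
c.299delAT	Frameshift	IC2	pathogenic	NA	NA	TRUE	31	4.71	2	0.43
c.341A>G	Glu114Gly	IC2	polymorphism	0.001	0.27	TRUE	25	3.80	9	1.95
c.368C>A	Thr123Asn	IC2	unknown	0.000	0.53	TRUE	5	0.76	1	0.22
c.504insAAGG	Frameshift	EC2	pathogenic	NA	NA	TRUE	2	0.30	0	0.00
c.571T>C	Phe191Leu	EC2	unknown	1.000	0.00	TRUE	4	0.61	0	0.00
c.605ins46	Stop at aa 202	TM4	pathogenic	NA	NA	TRUE	2	0.30	0	0.00
c.608TC>AA	Ile203Lys	TM4	pathogenic	NA	0.00	TRUE	2	0.30	0	0.00
c.608T>C	Ile203Thr	TM4	polymorphism	0.906	0.00	TRUE	2	0.30	1	0.22
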