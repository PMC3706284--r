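# Variant definitions pinning each catalogued legacy name to ref/alt strings
# on the synthetic stand-in references (gjb2_cds_synthetic.fa, mt12s_synthetic.fa).
# Insertions: position = coordinate of the first inserted base; ref_allele empty.
# m.961delT+insC is a delins (T replaced by a C run, canonical alt CC).
name	locus	kind	position	ref_allele	alt_allele
c.35delG	GJB2	deletion	35	G	
c.79G>A	GJB2	substitution	79	G	A
c.101T>C	GJB2	substitution	101	T	C
c.109G>A	GJB2	substitution	109	G	A
c.176del16	GJB2	deletion	176	AGAATTAACTGAAGTC	
c.235delC	GJB2	deletion	235	C	
c.257C>G	GJB2	substitution	257	C	G
c.299delAT	GJB2	deletion	299	AT	
c.341A>G	GJB2	substitution	341	A	G
c.368C>A	GJB2	substitution	368	C	A
c.504insAAGG	GJB2	insertion	504		AAGG
c.571T>C	GJB2	substitution	571	T	C
c.605ins46	GJB2	insertion	605		CATATCAGCGTCCCAAAAACGTTCGGACCTCAAAGCATCTATTCAC
c.608TC>AA	GJB2	mnv_substitution	608	TC	AA
c.608T>C	GJB2	substitution	608	T	C
m.663A>G	MT12S	substitution	663	A	G
m.681T>C	MT12S	substitution	681	T	C
m.709G>A	MT12S	substitution	709	G	A
m.735A>G	MT12S	substitution	735	A	G
m.750A>G	MT12S	substitution	750	A	G
m.752C>T	MT12S	substitution	752	C	T
m.789T>C	MT12S	substitution	789	T	C
m.827A>G	MT12S	substitution	827	A	G
m.961insC	MT12S	insertion	961		C
m.961delT+insC	MT12S	delins	961	T	CC
m.961T>C	MT12S	substitution	961	T	C
m.979C>T	MT12S	substitution	979	C	T
m.1005T>C	MT12S	substitution	1005	T	C
m.1009C>T	MT12S	substitution	1009	C	T
m.1040T>C	MT12S	substitution	1040	T	C
m.1041A>G	MT12S	substitution	1041	A	G
m.1048C>T	MT12S	substitution	1048	C	T
m.1095T>C	MT12S	substitution	1095	T	C
m.1107T>C	MT12S	substitution	1107	T	C
m.1119T>C	MT12S	substitution	1119	T	C
m.1187T>C	MT12S	substitution	1187	T	C
m.1222A>G	MT12S	substitution	1222	A	G
m.1282G>A	MT12S	substitution	1282	G	A
m.1382A>C	MT12S	substitution	1382	A	C
m.1415G>A	MT12S	substitution	1415	G	A
m.1438A>G	MT12S	substitution	1438	A	G
m.1494C>T	MT12S	substitution	1494	C	T
m.1520T>C	MT12S	substitution	1520	T	C
m.1555A>G	MT12S	substitution	1555	A	G
m.1598G>A	MT12S	substitution	1598	G	A
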