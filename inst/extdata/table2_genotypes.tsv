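# GJB2 genotype strata in cases (N=658) and controls (N=462).  allele1/allele2 are
# comma-separated variant names carried in cis on that allele, "-" = wild type.
# Subjects not covered by any stratum carry no GJB2 variant.
# Resolution log: the monoallelic c.109G>A control count is 4 (carrier-table total;
# the genotype table prints 3 het — one control carrier is unaccounted there), so
# that stratum-derived control carrier counts reconcile with the per-variant table
# for every pathogenic variant and the control pathogenic total is 11 (2.38%).
# The typographically garbled stratum around the two-variant-in-cis genotype is
# resolved from the phenotype table: allele1 = c.341A>G, allele2 = c.341A>G,c.79G>A,
# 2 cases / 0 controls.
allele1	allele2	stratum	case_count	control_count
c.35delG	-	pathogenic_monoallelic	1	0
c.109G>A	-	pathogenic_monoallelic	7	4
c.176del16	-	pathogenic_monoallelic	6	2
c.235delC	-	pathogenic_monoallelic	40	3
c.299delAT	-	pathogenic_monoallelic	12	2
c.504insAAGG	-	pathogenic_monoallelic	2	0
c.608TC>AA	-	pathogenic_monoallelic	2	0
c.35delG	c.235delC	pathogenic_biallelic	1	0
c.109G>A	c.109G>A	pathogenic_biallelic	8	0
c.176del16	c.176del16	pathogenic_biallelic	7	0
c.176del16	c.235delC	pathogenic_biallelic	5	0
c.176del16	c.299delAT	pathogenic_biallelic	3	0
c.235delC	c.235delC	pathogenic_biallelic	52	0
c.235delC	c.299delAT	pathogenic_biallelic	4	0
c.257C>G	c.605ins46	pathogenic_biallelic	2	0
c.299delAT	c.299delAT	pathogenic_biallelic	12	0
c.79G>A	-	polymorphism_unknown	64	28
c.101T>C	-	polymorphism_unknown	3	1
c.79G>A	c.79G>A	polymorphism_unknown	49	13
c.79G>A	c.341A>G	polymorphism_unknown	9	1
c.341A>G	c.341A>G	polymorphism_unknown	5	1
c.341A>G	c.341A>G,c.79G>A	polymorphism_unknown	2	0
c.79G>A	c.368C>A	polymorphism_unknown	11	3
c.608T>C	c.608T>C	polymorphism_unknown	4	0
c.368C>A	-	polymorphism_unknown	1	1
c.571T>C	-	polymorphism_unknown	4	0
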