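model	mirna_length	unpaired_positions	target_insertions	expected_class	expected_repressed	note
CDS1	22	3;4;5		NONFUNCTIONAL	FALSE	seed mismatched, miRNA 3' end fully paired
CDS1a	22	3;4;5;20;21;22		NONFUNCTIONAL	FALSE	seed mismatched, 3' end also unpaired
CDS2	22	5		NONFUNCTIONAL	FALSE	minor single-base seed imperfection, 3' paired
CDS2a	22	5;20;21;22		NONFUNCTIONAL	FALSE	minor seed imperfection, 3' end unpaired
CDS3	22			SLICING	TRUE	perfect complementarity across the interface
CDS3a	22	15		SLICING	TRUE	seed+central paired, one supplementary mismatch
CDS3b	22	21;22		SLICING	TRUE	two bases mismatched at the miRNA 3' end
CDS3c	22	20;21;22		SLICING	TRUE	seed pairing retained, 3' end left unpaired
DAPK3	22	4;5		NONFUNCTIONAL	FALSE	seed-mismatch reporter replicated from prior work
C-miR2	21	12		REPRESSIVE	TRUE	single central mismatch at position 12
C-miR2/11	21	11		REPRESSIVE	TRUE	single central mismatch at position 11
C-miR2/10	21	10		REPRESSIVE	TRUE	single central mismatch at position 10
C-miR2-11-12	21	11;12		WEAK	TRUE	two-base central bulge, severely reduced efficacy
C-miR2-10-13	21	10;11;12;13		NONFUNCTIONAL	FALSE	four-base central bulge abolishes activity
C-miR2-20-21	21	12;20;21		REPRESSIVE	TRUE	central mismatch plus two 3'-terminal mismatches
C-miR2-19-21	21	12;19;20;21		REPRESSIVE	TRUE	central mismatch plus three 3'-terminal mismatches
C-miR2-21-23	23	12;21;22;23		REPRESSIVE	TRUE	longer miRNA, three unpaired 3' bases, 8/9 3'-half pairs kept
siR2	21			SLICING	TRUE	fully complementary siRNA control
siR2-20-21	21	20;21		SLICING	TRUE	full central pairing, two unpaired 3'-terminal bases
siR2-19-21	21	19;20;21		SLICING	TRUE	full central pairing, three unpaired 3'-terminal bases
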