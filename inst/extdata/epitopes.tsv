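# Default CD-relevant alpha-gliadin peptide motifs.
# Peptide strings are literature-derived defaults (DQ2.5-restricted T-cell
# epitope registry sequences and the two major p31-43 variant forms); they
# are configuration data and can be overridden with a user table.
# Categories: 33mer_constituent (the three epitopes whose overlapping copies
# make up the 33-mer), flanking_dq2 (DQ2.5 epitope adjacent to the 33-mer),
# innate_peptide (non-T-cell innate response peptide; does not count toward
# CD-epitope status).
name	peptide	category
DQ2.5-glia-a1a	PFPQPQLPY	33mer_constituent
DQ2.5-glia-a1b	PYPQPQLPY	33mer_constituent
DQ2.5-glia-a2	PQPQLPYPQ	33mer_constituent
DQ2.5-glia-a3	FRPQQPYPQ	flanking_dq2
p31-43_LG	LGQQQPFPPQQPY	innate_peptide
p31-43_LP	LPQQQPFPPQQPY	innate_peptide
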