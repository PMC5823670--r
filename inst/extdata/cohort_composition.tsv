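cohort	cancer_type	stage	n
discovery	CC	I	10
discovery	CC	II	78
discovery	CC	III	63
discovery	CC	IV	22
discovery	RC	I	12
discovery	RC	II	34
discovery	RC	III	43
discovery	RC	IV	11
pfs	CC	I	10
pfs	CC	II	67
pfs	CC	III	55
pfs	CC	IV	4
pfs	RC	I	6
pfs	RC	II	31
pfs	RC	III	39
pfs	RC	IV	5
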