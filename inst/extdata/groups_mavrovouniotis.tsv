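group	contribution_kj_mol	source
origin	-103.4	mavrovouniotis
OH- (secondary)	-131.5	mavrovouniotis
-O- (ring)	-101.7	mavrovouniotis
>CH2	7.1	mavrovouniotis
>CH- (ring)	-10.9	mavrovouniotis
OH- (primary)	-119.7	mavrovouniotis
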