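group	contribution_kj_mol	source
origin	0.0	jankowski
OH- (secondary)	-173.8	jankowski
-O- (ring)	-153.2	jankowski
>CH2	6.8	jankowski
>CH- (ring)	20.3	jankowski
OH- (primary)	-173.8	jankowski
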