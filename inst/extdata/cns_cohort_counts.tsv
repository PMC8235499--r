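variable	category	n
total	ALL	439
diagnosis1	NEOPLASM	195
diagnosis1	CONTROL	244
diagnosis2	MALIGNANCY	154
diagnosis2	BENIGN	41
diagnosis2	CONTROL	244
grade	I	53
grade	II	18
grade	III	12
grade	IV	92
grade	CONTROL	244
grade	NOT_AVAILABLE	20
gender	FEMALES	97
gender	MALES	165
gender	FETUS	6
gender	NOT_AVAILABLE	171
sampling	VIVUS	181
sampling	POST-MORTEM	200
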