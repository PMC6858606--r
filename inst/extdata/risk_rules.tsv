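label	gleason_min	gleason_max	stage_min	stage_max
LR	NA	6	NA	T2a
HR	8	NA	NA	NA
HR	NA	NA	T2c	NA
IR	NA	NA	NA	NA
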