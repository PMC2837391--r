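label	control_tpm	treatment_tpm	printed_log2fc	digits	printed_p
S-adenosylmethionine synthetase (signature 1)	4038	2534	0.7	1	NA
S-adenosylmethionine synthetase (signature 2)	579	142	2.0	1	NA
S-adenosylmethionine synthetase (signature 3)	826	286	1.5	1	NA
S-adenosylhomocysteine hydrolase	636	291	1.13	2	1.92E-28
Transketolase	173	31	2.5	1	3.24E-23
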