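gene	definition	r_squared	p_value	size
atpE	F-type H+-transporting ATPase subunit c [EC:3.6.3.14]	0.952	4.82E-02	8
CETN2	centrin-2	0.995	4.62E-03	2
metK	S-adenosylmethionine synthetase [EC:2.5.1.6]	0.994	5.73E-03	2
petF	ferredoxin	0.953	4.70E-02	2
psaC	photosystem I subunit VII	0.910	8.95E-02	2
psaE	photosystem I subunit IV	0.974	2.57E-02	2
rbcL	ribulose-bisphosphate carboxylase large chain [EC:4.1.1.39]	0.998	2.16E-03	4
SMD2	small nuclear ribonucleoprotein D2	0.927	7.33E-02	3
tktB	transketolase [EC:2.2.1.1]	0.992	8.12E-03	2
YWHA	tyrosine 3-monooxygenase	0.949	5.13E-02	2
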