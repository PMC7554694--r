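set	member	sign
OXPHOS_TOY	SYN0001	1
OXPHOS_TOY	SYN0002	1
OXPHOS_TOY	SYN0003	1
OXPHOS_TOY	SYN0004	1
OXPHOS_TOY	SYN0005	1
OXPHOS_TOY	SYN0006	1
TCA_TOY	SYN0007	1
TCA_TOY	SYN0008	1
TCA_TOY	SYN0009	1
TCA_TOY	SYN0010	1
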