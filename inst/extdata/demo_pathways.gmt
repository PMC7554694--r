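OXPHOS_TOY	synthetic oxidative-phosphorylation-like demo set	SYN0001	SYN0002	SYN0003	SYN0004	SYN0005	SYN0006
TCA_TOY	synthetic TCA-cycle-like demo set	SYN0007	SYN0008	SYN0009	SYN0010
RIBOSOME_TOY	synthetic housekeeping demo set	SYN0011	SYN0012	SYN0013	SYN0014	SYN0015
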