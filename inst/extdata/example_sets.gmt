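glycolysis	toy glycolysis genes	g00001	g00002	g00003	g00004	g00005
fatty_acid_synthesis	toy lipogenesis genes	g00006	g00007	g00008	g00009
oxphos	toy oxidative phosphorylation genes	g00010	g00011	g00012	g00013	g00014	g00015
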