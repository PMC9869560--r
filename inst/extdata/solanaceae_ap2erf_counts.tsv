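species	previously_annotated	newly_annotated
Oryza sativa	163	14
Arabidopsis thaliana	141	1
Nicotiana benthamiana	323	32
Petunia axillaris	187	32
Capsicum annuum	181	67
Capsicum baccatum	173	74
Solanum tuberosum	212	42
Solanum melongena	153	23
Solanum pimpinellifolium	127	59
Solanum lycopersicum	167	24
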