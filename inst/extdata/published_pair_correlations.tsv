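pair	Flycatchers	Crows	Willow_warblers	Blackcaps	Greenish_warblers	Stonechats	Thrushes	Winged_warblers
Flycatchers	NA	0.17	0.21	0.23	NA	0.51	0.11	0.17
Crows	0.058	NA	0.09	0.14	NA	0.21	0.04	0.22
Willow_warblers	0.020	0.028	NA	0.29	NA	0.12	0.19	0.24
Blackcaps	-0.017	0.037	0.029	NA	NA	0.18	0.44	0.42
Greenish_warblers	0.11	0.054	-0.020	0.021	NA	NA	NA	NA
Stonechats	0.18	0.099	0.030	0.045	0.14	NA	0.37	0.11
Thrushes	0.084	0.024	0.12	0.0099	0.11	0.13	NA	0.21
Winged_warblers	0.0077	0.036	0.055	0.052	0.027	0.032	0.099	NA
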