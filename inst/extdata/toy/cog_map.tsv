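cluster_id	cog
OG_gen1	G
OG_gen2	G
OG_gen3	E
OG_gen4	GE
OG_gen5	V
OG_gen6	K
OG_gen8	G
OG_speA1	G
OG_speA3	E
OG_speB1	K
OG_speB3	P
OG_core1	J
OG_core2	J
OG_core3	L
OG_core4	K
OG_core5	E
OG_sing2	S
OG_bg1	R
OG_bg3	S
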