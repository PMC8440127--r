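cluster_id	a1	a2	a3	a4	a5	a6	b1	b2	b3	b4	b5	b6
OG_gen1	*	*	*	*	a5_OG_gen1	a6_OG_gen1	b1_OG_gen1	*	*	*	*	*
OG_gen2	*	*	*	*	*	a6_OG_gen2	b1_OG_gen2	b2_OG_gen2	b3_OG_gen2	*	*	*
OG_gen3	*	*	*	*	*	a6_OG_gen3	b1_OG_gen3	b2_OG_gen3	b3_OG_gen3	*	*	*
OG_gen4	*	*	*	*	*	a6_OG_gen4	b1_OG_gen4	b2_OG_gen4	b3_OG_gen4	*	*	*
OG_gen5	*	*	*	*	*	a6_OG_gen5	b1_OG_gen5	b2_OG_gen5	b3_OG_gen5	*	*	*
OG_gen6	*	*	*	*	*	a6_OG_gen6	b1_OG_gen6	b2_OG_gen6	b3_OG_gen6	*	*	*
OG_gen7	*	*	*	*	*	a6_OG_gen7	b1_OG_gen7	b2_OG_gen7	b3_OG_gen7	*	*	*
OG_gen8	*	*	*	*	*	a6_OG_gen8	b1_OG_gen8	b2_OG_gen8	b3_OG_gen8	*	*	*
OG_speA1	a1_OG_speA1	a2_OG_speA1	*	*	*	*	*	*	*	*	*	*
OG_speA2	a1_OG_speA2	a2_OG_speA2	*	*	*	*	*	*	*	*	*	*
OG_speA3	a1_OG_speA3	a2_OG_speA3	*	*	*	*	*	*	*	*	*	*
OG_speB1	*	*	*	*	*	*	*	*	*	b4_OG_speB1	b5_OG_speB1	*
OG_speB2	*	*	*	*	*	*	*	*	*	b4_OG_speB2	b5_OG_speB2	*
OG_speB3	*	*	*	*	*	*	*	*	*	b4_OG_speB3	b5_OG_speB3	*
OG_core1	a1_OG_core1	a2_OG_core1	a3_OG_core1	a4_OG_core1	a5_OG_core1	a6_OG_core1	b1_OG_core1	b2_OG_core1	b3_OG_core1	b4_OG_core1	b5_OG_core1	b6_OG_core1
OG_core2	a1_OG_core2	a2_OG_core2	a3_OG_core2	a4_OG_core2	a5_OG_core2	a6_OG_core2	b1_OG_core2	b2_OG_core2	b3_OG_core2	b4_OG_core2	b5_OG_core2	b6_OG_core2
OG_core3	a1_OG_core3	a2_OG_core3	a3_OG_core3	a4_OG_core3	a5_OG_core3	a6_OG_core3	b1_OG_core3	b2_OG_core3	b3_OG_core3	b4_OG_core3	b5_OG_core3	b6_OG_core3
OG_core4	a1_OG_core4	a2_OG_core4	a3_OG_core4	a4_OG_core4	a5_OG_core4	a6_OG_core4	b1_OG_core4	b2_OG_core4	b3_OG_core4	b4_OG_core4	b5_OG_core4	b6_OG_core4
OG_core5	a1_OG_core5	a2_OG_core5	a3_OG_core5	a4_OG_core5	a5_OG_core5	a6_OG_core5	b1_OG_core5	b2_OG_core5	b3_OG_core5	b4_OG_core5	b5_OG_core5	b6_OG_core5
OG_sing1	*	*	a3_OG_sing1,a3_OG_sing1b	*	*	*	*	*	*	*	*	*
OG_sing2	*	*	*	*	*	*	*	*	*	*	*	b6_OG_sing2
OG_bg1	*	*	a3_OG_bg1	a4_OG_bg1	*	*	*	*	*	*	*	b6_OG_bg1
OG_bg2	*	*	*	a4_OG_bg2	*	*	*	*	*	*	*	b6_OG_bg2
OG_bg3	*	*	a3_OG_bg3	*	*	*	*	*	*	*	*	b6_OG_bg3
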