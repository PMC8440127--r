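planted_generalist_clusters:
- OG_gen2
- OG_gen3
- OG_gen4
- OG_gen5
- OG_gen6
- OG_gen7
- OG_gen8
planted_specialist_clusters:
- OG_speA1
- OG_speA2
- OG_speA3
- OG_speB1
- OG_speB2
- OG_speB3
planted_core_clusters:
- OG_core1
- OG_core2
- OG_core3
- OG_core4
- OG_core5
planted_communities:
- - a6
  - b1
  - b2
  - b3
generalist_strains:
- a6
- b1
- b2
- b3
specialist_strains:
- a1
- a2
- b4
- b5
true_beta: 10000.0
seed: .na.integer
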