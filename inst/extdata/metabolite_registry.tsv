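metabolite	carbon_count	network_node	secreted
acetate	2	acetyl_coa	TRUE
succinate	4	succinyl_coa	TRUE
formate	1	pyruvate	TRUE
propionate	3	succinyl_coa	TRUE
lactate	3	pyruvate	TRUE
histidine	6	purine	TRUE
cysteine	3	serine_cycle	TRUE
cystine	6	serine_cycle	TRUE
glutathione	10	serine_cycle	TRUE
asparagine	4	oxaloacetate_aspartate	TRUE
alanine	3	oxaloacetate_aspartate	TRUE
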