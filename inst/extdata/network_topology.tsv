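from	to
glucose	pyruvate
pyruvate	acetyl_coa
pyruvate	oxaloacetate_aspartate
pyruvate	serine_cycle
oxaloacetate_aspartate	succinyl_coa
serine_cycle	purine
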