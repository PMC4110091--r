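type	count	excluded
blast	5	FALSE
death	131	TRUE
epithelial	262	FALSE
germ	2	FALSE
gland	13	FALSE
intestinal	20	FALSE
muscle	153	FALSE
neural_structural	46	FALSE
neuron	305	FALSE
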