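type	count	excluded
blast	39	FALSE
death	113	TRUE
epithelial	93	FALSE
germ	2	FALSE
gland	13	FALSE
intestinal	20	FALSE
muscle	123	FALSE
neural_structural	46	FALSE
excretory_canal_neuron	2	FALSE
interneuron	95	FALSE
motor_neuron	45	FALSE
polymodal_neuron	26	FALSE
sensory_neuron	54	FALSE
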