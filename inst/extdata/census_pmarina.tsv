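type	count	excluded
body_muscle	81	FALSE
death	67	TRUE
germ	2	FALSE
hypodermis	131	FALSE
intestine	20	FALSE
nervous_system	195	FALSE
pharynx	112	FALSE
unknown	30	FALSE
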