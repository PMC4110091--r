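type	count	excluded
endoderm	12	FALSE
epidermis	50	FALSE
mesenchyme	6	FALSE
muscle	10	FALSE
nervous_system	16	FALSE
notochord	10	FALSE
undifferentiated	6	FALSE
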