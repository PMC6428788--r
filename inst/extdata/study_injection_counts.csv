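group,n_animals,n_injections
comparator,5,58
planned,5,60
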