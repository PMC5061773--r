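>TUA1_TUA5_nterm_synthetic species=Pd family=TUA span=1-60 terminal_met=0
MRECISIHIGQAGIQVGNACWELYCLEHGIQPDGQMPSDKTVGGGDDAFNTFFSETGAGK
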