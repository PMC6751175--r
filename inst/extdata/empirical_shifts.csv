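set,condition,action_shift_ms,outcome_shift_ms
haggard,voluntary,15,-46
haggard,involuntary,-27,31
haggard,sham,-7,-8
wolpe,low,39,-51
wolpe,intermediate,31,-65
wolpe,high,32,-105
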