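metric,count
tp,159
fp,79
fn,37
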