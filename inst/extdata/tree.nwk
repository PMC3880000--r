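(((GSO:1,ACU:1):1,LCO:1):1,MCA:1);
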