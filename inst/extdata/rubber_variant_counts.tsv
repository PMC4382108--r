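kind	count
snp	340631
deletion	8293
insertion	17272
complex	2398
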