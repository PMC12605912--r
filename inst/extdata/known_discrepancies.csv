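drug,detail
Olaparib,"Transcribed structure (C24H23FN4O3) matches the published |V|=32, |E|=36 but exhaustive solving yields (beta=4, eta=13, xi1=14, xi2=16) where the published invariant table prints (3, 8, 10, 23); the published drawing is not machine-readable, so the disagreement cannot be arbitrated and is reported rather than patched."
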