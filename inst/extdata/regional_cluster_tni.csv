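cluster,tni,fe_richness
SC-1,621,15
SC-2,1213,19
SC-3,1147,18
SC-4,751,15
SC-5,890,17
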