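"pressure_mmHg","raw_freq"
750,1513.95
850,1713.77
950,1913.59
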