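"district","rice_area_ha"
"D01",77268
"D02",147859
"D03",102563
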