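region_id	completeness	quality
Bath-R1	76.28	Medium-quality
Bath-R2	100.0	High-quality
KN2-R1	60.97	Medium-quality
KN2-R2	60.91	Medium-quality
IO1-R1	100.0	High-quality
McNor-R1	70.28	Medium-quality
McNor-R2	73.14	Medium-quality
McNor-R3	69.54	Medium-quality
16-5-R1	100.0	High-quality
16-5-R2	100.0	High-quality
16-5-R3	100.0	High-quality
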