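# expected magnitude of the secondary chemical shift (ppm) in fully formed
# helix / sheet, used to scale SSP scores; replaceable by the user
nucleus	helix_ppm	sheet_ppm
CA	2.6	1.4
CB	1.4	2.2
CO	2.1	1.5
HA	0.39	0.37
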