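#junction_offset=3
A	C	G	T
0.33	0.36	0.18	0.13
0.6	0.13	0.14	0.13
0.09	0.05	0.78	0.08
0.001	0.001	0.997	0.001
0.001	0.001	0.001	0.997
0.6	0.05	0.28	0.07
0.7	0.08	0.1	0.12
0.08	0.06	0.8	0.06
0.17	0.16	0.19	0.48
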