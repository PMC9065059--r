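#junction_offset=20
A	C	G	T
0.1	0.32	0.1	0.48
0.1	0.32	0.1	0.48
0.1	0.32	0.1	0.48
0.1	0.32	0.1	0.48
0.1	0.32	0.1	0.48
0.1	0.32	0.1	0.48
0.1	0.32	0.1	0.48
0.1	0.32	0.1	0.48
0.1	0.32	0.1	0.48
0.1	0.32	0.1	0.48
0.1	0.32	0.1	0.48
0.1	0.32	0.1	0.48
0.1	0.32	0.1	0.48
0.1	0.32	0.1	0.48
0.1	0.32	0.1	0.48
0.1	0.32	0.1	0.48
0.25	0.3	0.21	0.24
0.06	0.65	0.01	0.28
0.997	0.001	0.001	0.001
0.001	0.001	0.997	0.001
0.28	0.14	0.49	0.09
0.25	0.25	0.25	0.25
0.25	0.25	0.25	0.25
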