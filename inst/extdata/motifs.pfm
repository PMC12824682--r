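>ETS_like
A 0.05 0.05 0.85 0.85 0.10 0.05
C 0.05 0.05 0.05 0.05 0.10 0.45
G 0.85 0.85 0.05 0.05 0.70 0.05
T 0.05 0.05 0.05 0.05 0.10 0.45
>GATA_like
A 0.10 0.80 0.05 0.80 0.05 0.10
C 0.10 0.05 0.05 0.05 0.05 0.30
G 0.70 0.05 0.05 0.10 0.85 0.30
T 0.10 0.10 0.85 0.05 0.05 0.30
>CG_box
A 0.05 0.05 0.05 0.05 0.05 0.05
C 0.45 0.85 0.05 0.45 0.85 0.05
G 0.45 0.05 0.85 0.45 0.05 0.85
T 0.05 0.05 0.05 0.05 0.05 0.05
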