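# inversion-recovery brain TSE
fov: [160, 192, 256]
matrix: [40, 48, 64]
tr: 3000
te: 20
ti: 100
etl: 40
bandwidth: 20000
ordering: center_out
elliptical: true
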