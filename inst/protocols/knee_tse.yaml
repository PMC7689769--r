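# knee 3D TSE; the figure-caption timing (TE/TR = 10/130 ms, full
# phase-encode coverage) reproduces the printed 11 min 50 s scan time
fov: [256, 256, 256]
matrix: [128, 128, 128]
tr: 130
te: 10
etl: 3
bandwidth: 20000
ordering: center_out
elliptical: false
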