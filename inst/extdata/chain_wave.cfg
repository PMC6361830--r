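# chain-wave experiment: 40 cells, slowed D-current inactivation
n_cells = 40
h_dtau = 3000
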