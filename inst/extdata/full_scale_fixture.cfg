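# full-scale fixture: 5_1-knotted N = 500 ring, equilibrated for one chain
# relaxation time (1e5 tau_B). Hours of CPU; shipped for completeness, the
# test suite exercises the scaled-down configurations instead.
N = 500
q = 5
lp = 20
equil_steps = 1e7
seed = 1
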