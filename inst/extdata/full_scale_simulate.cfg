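# full-scale relaxation run: one TopoII segment (50 beads) relocating by
# random jumps at k_j = 1e-2 per tau_B over 1e5 tau_B. Repeat over >= 64
# replicas (vary seed) and feed the trajectories to `analyze`.
lp = 20
mode = jump
l_T = 50
k_j = 1e-2
k_d = 0
A_soft = 2
A_unbind = 20
ramp_duration = 100
n_steps = 1e7
sample_every = 1e4
format = xyz
seed = 1
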