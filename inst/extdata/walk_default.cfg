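# knot-space walk, defaults: 1000 walkers from the 5_1 disk centre,
# ~300 jumps per time unit
model = ii
n_walkers = 1000
horizon = 30
dt = 1e-3
D_walk = 0.5
jump_rate = 300
seed = 1
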