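# High-density CDI competition, desk scale (fast inhibition, full toxicity)
alpha = 1.38629436111989
eta = 1
delta = 1
mu = 0.01
beta = 0
dt = 0.05
n_steps = 350
inoculum_radius = 50
inoculum_density = 160
inhibitor_fraction = 0.5
seed = 1
snapshot_interval = 50
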