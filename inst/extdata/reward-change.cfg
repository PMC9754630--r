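# Reward-change task: reward steps from R1 to R2 at t = 0.5
schema_version: 1
kind: reward
R1: 3
R2: 8
m: 5
sigma: 1
cost: 1
Ri: 0
ti: 1
delta_t: 0.01
window: 1
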