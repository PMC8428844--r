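name: chemostat_gamma1
mode: chemostat
seed: 1
tradeoff: {gamma: 1.0, budget: 1.0}
environment:
  supply: [1.0, 1.0, 1.0]
  monod_K: [1.0, 1.0, 1.0]
  decay: [0.1, 0.1, 0.1]
  death_rate: 1.0
evolution: {mutation_sigma: 0.03, mutations_per_epoch: 5, epoch_duration: 100, mutant_fraction: 0.01, max_epochs: 3000}
initial: [0.8, 0.15, 0.05]
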