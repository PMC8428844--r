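name: serial_gamma09_cK
mode: dilution
seed: 1
tradeoff: {gamma: 0.9, budget: 1.0}
environment:
  supply: [1.0, 1.0, 1.0]
  monod_K: [1.0, 1.0, 1.0]
  decay: [0.0, 0.0, 0.0]
  death_rate: 0.0
dilution: {rho0: 1.0e-3, c_init: [1.0, 1.0, 1.0], c_fin: 1.0e-8, n_batches: 1}
evolution: {mutation_sigma: 0.03, mutations_per_epoch: 5, epoch_batches: 5, mutant_fraction: 0.01, max_epochs: 3000}
initial: [0.8, 0.15, 0.05]
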