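# Desk-scale demonstration configuration: three-state test landscape with
# basin depths of -5 / -2.5 kBT and a ~6 kBT escape barrier at 310 K.
landscape: test
langevin:
  dt: 0.05
  D_x: 0.1
  D_theta: 10
  temperature: 310
  n_steps: 400000
metad:
  h0: 0.25
  stride: 20
  deltaT: 5115
  sigma_x: 0.25
  sigma_theta: 2.06
  n_run: 2
kinetics:
  n_runs: 6
  boundary_x: 6.5
thermo:
  temperature: 310
temperatures: [310, 300, 290]
seed: 1
outdir: metakin_out
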