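# Demonstration run: fully synthetic inputs, every stage enabled.
# All values shown are the package defaults; edit and pass to
# run_pipeline() (or read_run_config()) to customise.
run_dir: ppiasekit_run
seed: 1
simulate:
  # sequence/sites omitted: the built-in synthetic substrate with two
  # planted proline-aromatic sites is used
  ratios: [0.1, 0.2, 0.5, 1, 2]
  noise_sd: 0.02
  kd: 4.7e-05
profile:
  window: 9
  threshold: 0
titrate:
  significance: mad
  k: 2
  min_run: 5
  bridge_missing: true
cpmg:
  r2_0: 15
  kex: 740
  phi: 2000
  noise_sd: 0.3
  t_relax: 0.05
  field_mhz: 800
  delta_omega_ppm: 0.8
torsion:
  n_residues: 5
  proline_index: 3
  start_omega: -174
  end_omega: 0
  step: 0.2
  dwell: 2
  direction: clockwise
  contact_distance: 2.2
thermo:
  kd: 4.7e-05
  temperature: 295.15
  dh: -5.9
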