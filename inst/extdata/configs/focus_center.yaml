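# SSAW focusing, single pressure node on the channel centerline.
scenario: focus
geometry:
  width: 1.6e-4        # channel width (m)
  ny: 80               # lattice nodes across the width
  nx: 40               # axial nodes (periodic)
  re: 0.70             # axial-flow Reynolds number
  initial_y: 7.0e-5    # initial lateral particle position (m)
fluid:
  density: 1027        # kg/m^3
  viscosity: 1.0e-6    # m^2/s
  compressibility: 4.5e-10  # 1/Pa
  lattice_viscosity: 0.0167
particle:              # 10 um polystyrene
  radius: 5.0e-6
  density: 1050
  compressibility: 2.49e-10
acoustic:
  wavelength: 3.2e-4   # m (twice the channel width: node at the centerline)
  energy_density: 400  # J/m^3 (desk-scale calibration)
  active: true
numerics:
  max_steps: 200000
  steady_tol: 5.0e-7   # m
  steady_window: 5000  # lattice steps
output:
  dir: "."
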