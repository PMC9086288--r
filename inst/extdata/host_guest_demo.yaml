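# Demo configuration: the frozen 3D host-guest fixture, written out as the
# config file the CLI `simulate` subcommand consumes.
#
# For a real system (e.g. a solvated protein-ligand complex such as
# mitoNEET-furosemide, PDB 6DE9) the simulate stage is replaced by an
# all-atom engine; the keys below marked "all-atom only" are NOT understood
# by the toy engine and are listed here, commented out, purely as a record
# of what a production setup would additionally specify:
#
#   thermostat: nose-hoover      # all-atom only (out of scope here)
#   barostat: parrinello-rahman  # all-atom only (out of scope here)
#   forcefield: amber14sb        # all-atom only (out of scope here)
#   water_model: tip3p           # all-atom only (out of scope here)
#
# The analysis subcommands (reweight/fes/basins/deltag) work on any
# PLUMED-style COLVAR/HILLS pair regardless of which engine produced it.

system:
  type: host_guest

langevin:
  timestep: 0.005      # ps
  friction: 2          # 1/ps
  temperature: 298     # K
  mass: 50             # amu
  n_steps: 400000      # 2 ns (short demo; the frozen fixture runs 8 ns)

metad:
  h0: 0.3              # kcal/mol
  stride: 1            # ps
  widths: [0.4, 0.1, 0.5235987755982988]   # A, -, rad (pi/6)
  gamma: 10
  periodic_theta: true
  confine: true

volume:
  origin: [0, 0, 0]
  axis: [1, 0, 0]
  k: 2.5               # A
  a0: -1               # A
  rho_max: 9           # A
  tau_max: 1.2
  wall_k: 20           # kcal/mol per squared CV unit
  a_min: 0.5           # A

contacts:
  n: 8
  m: 12
  d0: 0                # A
  r0: 2.5              # A

reweight:
  t_start_frac: 0.5
  n_blocks: 5

seed: 1
output_prefix: hostguest_demo
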