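# Reference configuration of the cryptdyn package.
#
# Values marked [calibrated] are not taken from a published table; they
# were chosen so that (a) the uniform Wnt/inhibitor fixed point is unique
# and stable at every progenitor density, (b) the pair is Turing-unstable
# near C0 = 1/2 with fastest mode 2 on the default domain, and (c) the
# de-novo formation scenario settles into a two-crypt steady state.
# Unmarked values are anchors of the reference parameterisation.

lineage:
  v0: 1                 # cellular time unit: one cell cycle / ln 2
  p0_max: 0.95
  gamma_W: 1.2          # [calibrated] p0 straddles 1/2 across the Wnt pattern
  n: 2
  gamma_B: 5            # [calibrated]
  m: 2
  d1_max: 0.15          # [calibrated] sets homeostatic length via mass balance
  d1_profile:
    name: constant      # or apex_localized (floor_frac, width_frac)

morphogen:
  D_W: 6.0e-8           # [calibrated] short-range activator
  D_I: 1.5e-6           # [calibrated] long-range inhibitor (D_I/D_W = 25)
  D_B: 2.0e-5
  mu0: 1.6e-3           # [calibrated] basal Wnt production per progenitor
  mu1: 2.5e-4           # BMP production per TD cell
  alpha_W: 6.0e-3       # [calibrated] Wnt self-activation
  alpha_I: 8.0e-3       # [calibrated] inhibitor synthesis
  beta_W: 1             # [calibrated]
  beta_I: 0.7           # [calibrated]
  beta_W_inh: 1         # [calibrated]
  n_W: 4                # [calibrated]
  m_W: 2
  n_I: 2
  d_W: 2.0e-3           # Wnt removal; the dW_scan scenario raises it up to 9x
  d_I: 2.0e-3
  d_B: 1.4e-3           # inside the stable-crypt removal window

geometry:
  epsilon0: 0.005
  baseline_b: 0
  endpoint_a: [-0.1, 0]
  endpoint_b: [0.1, 0]
  flow_rate: 50         # [calibrated] curve slaved quasi-statically
  energy_kind: tanh_wells
  count_threshold_frac: 0.1

numerics:
  dt: 2.0e-3
  t_end: 100
  n_points: 128
  qss_tol: 1.0e-9
  qss_tol_soft: 1.0e-5   # accepted near folds of the quasi-steady branch
  qss_max_iter: 40
  qss_relax_max: 4000
  qss_recheck_every: 200
  seed: 1
  snapshot_every: 10
  steady_tol: 1.0e-6
  steady_window: 1
  length_drive: production   # or geometry (curve-arclength driven)
  cfl_max: 0.5
  qss_include_advection: false
  strict_negative: false

scenario:
  name: formation
  init:
    kind: uniform_noisy_wnt
    c0: 0.5
    wnt_mean: 0.1
    noise_amplitude: 0.05
    n_modes: 16
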