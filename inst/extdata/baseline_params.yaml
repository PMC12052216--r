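# Baseline (healthy-healing) parameterisation of the dermal wound-healing
# Cellular Potts model. Units: lengths in pixels (3 um), time in MCS (27 s)
# unless the key name says _per_day/_days; field concentrations are arbitrary
# model units (only ratios to the thresholds below matter).
units:
  pixel_um: 3                      # um per lattice pixel
  seconds_per_mcs: 27              # 0.3 um/MCS * 3600 / (40 um/h)
  reference_displacement_um: 0.3   # reference displacement per MCS
  reference_speed_um_h: 40         # peak fibroblast migration speed
cpm:
  temperature: 3                   # Metropolis acceptance scale (calibrated to ~0.1 px/MCS free-cell speed)
  contact_energy:                  # symmetric J values (energy per pair)
    cell_cell: 11
    cell_medium: 7
    ecm_cell: 12
    ecm_medium: 12
    ecm_ecm: 2
  target_volume:                   # pixels
    fib: 64
    myo: 64
    mac: 64
    snc: 64
    pre: 64
    ecm: 1
  lambda_volume:                   # energy / pixel^2
    fib: 2
    myo: 2
    mac: 2
    snc: 2
    pre: 2
    ecm: 150
  target_surface:                  # Moore boundary pixel pairs
    fib: 92
    myo: 92
    mac: 92
    snc: 92
    pre: 92
    ecm: 8
  lambda_surface:
    fib: 0.2
    myo: 0.2
    mac: 0.2
    snc: 0.2
    pre: 0.2
    ecm: 0
chemotaxis:
  lambda_pdgf: 600                 # fibroblasts / myofibroblasts, up PDGF
  lambda_pdgf_ecm: 900             # strengthened while touching ECM
  lambda_inf: 600                  # macrophages, up inflammatory SASP
fields:                            # per MCS; pixel^2/MCS and 1/MCS
  pdgf: {diffusion: 1.0, decay: 0.001}   # signalling range ~30 px
  csf1: {diffusion: 1.0, decay: 0.0005}
  mmp:  {diffusion: 1.0, decay: 0.002}
  inf:  {diffusion: 1.0, decay: 0.0008}
secretion:                         # per cell per MCS (split over its pixels)
  pdgf_mac_m2: 0.9
  mmp_mac_m1: 1.0
  mmp_mac_ecm: 0.1
  csf1_fib: 0.15
  pdgf_myo: 0.6
  csf1_myo: 0.2
  pdgf_snc: 0.8
  csf1_snc: 0.5
  inf_snc: 1.6
  mmp_snc: 1.5
growth:
  gmax_fib: 0.036                  # pixels/MCS (doubling in ~13 h at saturation)
  gmax_myo: 0.036                  # pixels/MCS (~13 h)
  gmax_mac: 0.022
  pdgf0: 0.5                       # half-saturation concentrations
  csf0: 0.8
  t_ci: 0.1                        # contact-inhibition threshold on Rs
thresholds:                        # concentration units except ecm_thr (pairs)
  pdgf_f: 0.3
  snc_thr: 3.0
  mmp_thr: 0.3
  ecm_thr: 6
  inf_thr: 0.2
  csf1_thr: 0.005
rules:
  sweep_period_mcs: 50             # behaviour rules evaluated every K MCS
  p_mf: 0.1                        # myofibroblast differentiation (per 500-MCS step)
  p_snc: 0.15                      # primary senescence (per 500-MCS step)
  p_clear: 0.03                    # senescent clearance (per sweep, each trigger)
  mu: 0.05                         # activated fibroblast / macrophage removal (per day)
  t_sen: 12                        # senescence-induction gate time
  t_sen_unit: steps1000            # 12 x 1000 MCS = 3.75 days
  t_sen_gate: open_after           # induction permitted for t >= T_SEN
  t_nis_days: 3                    # fibrogenic SASP phase duration
  ecm_fib_per_day: 8               # ECM pixels per fibroblast per day
  ecm_myo_per_day: 16              # double the fibroblast amount
  ecm_snc_per_day: 8               # fibrogenic-phase senescent output
  p_dediff: 0                      # myofibroblast de-differentiation (off)
init:
  width: 200
  height: 200
  wound_margin: 40                 # dermal rim width; wound is the interior
  cell_block: 8                    # cells seeded as 8x8 blocks
  fib_fraction: 0.45               # dermal blocks that are fibroblasts (rest ECM)
  ecm_fraction: 0.7                # density of 1-px ECM in non-fibroblast dermis
  n_macrophages: 24                # M2 macrophages seeded in the wound
  n_preexisting: 0                 # inflammatory senescent cells at t = 0
  pre_inf_bolus: 30                # INF units deposited per pre-existing cell
  csf1_init: 0.5                   # initial uniform CSF1 (end of inflammation phase)
scenario:
  duration_days: 18
  replicates: 3
  sample_period_mcs: 500
  snapshot_days: [0, 1, 3, 5, 7, 12, 18]
classification:
  fibrosis_factor: 1.5             # final wound ECM > factor x baseline -> fibrotic
  deficit_factor: 0.65             # final wound ECM < factor x baseline -> chronic
  inflammation_factor: 1.45        # final INF or macrophages > factor x baseline -> chronic
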