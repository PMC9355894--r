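# iphase default run configuration.
# Units are embedded in key names (angstrom, ev, kev). Every pinned physical
# constant carries its provenance here; nothing below is fitted to outputs.
config_version: 1
beam:
  energy_kev: 300          # primary beam energy
  window_lo_ev: 13         # 4 eV filter slit centred on the 15 eV Al plasmon
  window_hi_ev: 17
  fluence_rate_e_per_a2_s: 15
  exposure_s: 4            # 60 e-/A^2 per image at these defaults
materials:
  Pt:
    # Elastic MFP from NIST-scale elastic cross sections (Z=78) at bulk
    # density 21.45 g/cm^3; only Pt's elastic MFP enters the simulation and
    # it cancels in every top/bottom ratio.
    lambda_el_angstrom: 75
    # Inelastic MFP: literature scale for dense transition metals at 300 keV.
    lambda_inel_angstrom: 800
    # Broad single-event loss table emulating the Pt energy-loss function
    # (interband + plasmon continuum); its mass in the 13-17 eV window is
    # 0.15, the effective config scalar the ratio logic depends on.
    loss:
      kind: tabulated
      table_ev: [4, 6, 8, 10, 12, 14, 16, 18, 20, 22, 24, 26, 28, 30]
      table_weight: [0.05, 0.10, 0.13, 0.12, 0.10, 0.08, 0.07,
                     0.065, 0.06, 0.055, 0.05, 0.045, 0.04, 0.035]
  Al:
    lambda_el_angstrom: 420    # NIST-scale elastic cross section, 2.70 g/cm^3
    # Free-electron plasmon MFP, relativistic kinematics:
    # lambda = 2 a0 m0 v^2 / (Ep ln(1+(qc/ (k0 thetaE))^2)) with Ep = 15 eV,
    # qc = 1.3 1/A, 300 keV -> 2223 A.
    lambda_inel_angstrom: 2220
    loss: {kind: delta, center_ev: 15}   # single plasmon; 30 eV = two events
  C:
    lambda_el_angstrom: 1080   # NIST-scale elastic cross section, 1.7 g/cm^3
    # Same formula with Ep = 23 eV (amorphous-carbon plasmon), qc = 1.5 1/A.
    lambda_inel_angstrom: 1540
    loss: {kind: delta, center_ev: 23}   # outside the 13-17 eV window
geometry:
  particle_diameter_angstrom: 50
  particle_height_angstrom: 33.5   # cylinder of equal volume to a 50 A sphere
  al_thickness_angstrom: 1100
  c_thickness_angstrom: 600
simulation:
  n_electrons: 1.0e+7
  n_repeats: 10
  seed: 1
synthesis:
  box_px: 250
  pixel_size_angstrom: 0.34
  defocus_min_angstrom: -3500
  defocus_max_angstrom: 3500
  defocus_step_angstrom: 250       # 29 frames
  pt_d_spacing_angstrom: 2.26      # Pt 111
  al_d_spacing_angstrom: 2.34      # Al 111
  pt_amplitude_median: 0.12
  al_amplitude: 0.10
  dispersion_sdlog: 0.32           # power SD/mean ~ 0.7 across particles
  min_angle_sep_deg: 10
measurement:
  d_target_angstrom: 2.26
  d_tol_angstrom: 0.05
  box_px: 250
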