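hand_mass_kg: 0.4
com_distance_m: 0.07
inertia_fe_kgm2: 0.002
inertia_rud_kgm2: 0.002
passive_stiffness_Nm_per_deg:
- 0.008
- 0.008
passive_damping_Nms_per_deg:
- 0.0006
- 0.0006
gravity_accel_m_s2: 9.81
muscles:
  names:
  - FCR
  - FCU
  - ECRL
  - ECRB
  - ECU
  - APL
  moment_arms_mm:
    FE:
    - 10.0
    - 14.0
    - -7.0
    - -12.0
    - -6.0
    - 4.0
    RUD:
    - -8.0
    - 12.0
    - -13.0
    - -3.0
    - 14.0
    - -15.0
  pcsa_cm2:
  - 2.0
  - 3.4
  - 2.2
  - 2.7
  - 2.6
  - 1.9
  f_lower_N:
  - 2.0
  - 2.0
  - 2.0
  - 2.0
  - 2.0
  - 2.0
  specific_tension_N_cm2: 35.0
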