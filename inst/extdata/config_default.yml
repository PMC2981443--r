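# Default run configuration. Any key omitted falls back to the
# constructor default; unknown keys are rejected.
material:
  sigma_max: 175      # MPa, avian bone breaking limit
  bending_share: 0.5  # fraction of Zp credited to one-plane bending
glide:
  rho: 1.23           # kg/m^3
  k_induced: 1.1
  cd_profile: 0.014
  cd_body: 0.1
  cl_max_unsteady: 2.2
  cl_max_steady: 1.8
  min_span_fraction: 0.8
  flap_glide_ratio: 0.2
burst:
  muscle_fraction: 0.3   # flight muscle as fraction of body mass
  specific_power: 400    # W/kg, anaerobic burst output
  burst_duration: 60     # s
  climb_rate: 1          # m/s
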