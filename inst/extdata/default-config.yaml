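# Standard solutions and voltage protocols for RPE whole-cell K+ recordings.
# Concentrations in mM, potentials in mV, durations in ms, temperature in K.
#
# Assumptions (overridable): the free K+ of Ames' medium is not printed on
# the formulation and defaults to 3.6 mM; pipette K+ totals the K salts
# (25 KCl + 83 K-gluconate = 108 mM), ignoring KOH titration.
solutions:
  pipette:
    name: kcl_gluconate_pipette
    concentrations_mM: {K: 108, Na: 5.1, Cl: 33, Ca: 0.5, Mg: 4}
    temperature_K: 295
    ljp_mV: 0
  ames:
    name: ames
    concentrations_mM: {K: 3.6, Na: 154, Cl: 130, Ca: 1.15, Mg: 1.2}
    temperature_K: 295
    ljp_mV: 0            # LJP negligible in Ames'
  na_based:
    name: na_based
    concentrations_mM: {K: 3, Na: 120, Cl: 127.6, Ca: 1.1, Mg: 1.2}
    temperature_K: 295
    ljp_mV: 11           # measured
  rb_based:
    name: rb_based
    concentrations_mM: {K: 3, Rb: 120, Na: 0, Cl: 127.6, Ca: 1.1, Mg: 1.2}
    temperature_K: 295
    ljp_mV: 4            # measured

protocols:
  outward_50ms:          # delayed-rectifier survey
    holding_mV: -45
    step_start_mV: -45
    step_stop_mV: 45
    step_increment_mV: 10
    step_duration_ms: 50
    holding_duration_ms: 50
    sample_interval_ms: 0.1
  sustained_1000ms:      # M-current / A-type survey
    holding_mV: -70
    step_start_mV: -70
    step_stop_mV: 40
    step_increment_mV: 10
    step_duration_ms: 1000
    holding_duration_ms: 50
    sample_interval_ms: 0.1
  tail_gv:               # tail-current conductance analysis
    holding_mV: -10
    step_start_mV: -100
    step_stop_mV: 40
    step_increment_mV: 10
    step_duration_ms: 1000
    holding_duration_ms: 50
    tail_mV: -10
    tail_duration_ms: 500
    sample_interval_ms: 0.1
  tail_gv_deep:          # deeper prepulse variant of the same analysis
    holding_mV: -10
    step_start_mV: -140
    step_stop_mV: 40
    step_increment_mV: 10
    step_duration_ms: 1000
    holding_duration_ms: 50
    tail_mV: -10
    tail_duration_ms: 500
    sample_interval_ms: 0.1
  kir_iv:                # inward-rectifier survey
    holding_mV: -45
    step_start_mV: -145
    step_stop_mV: 45
    step_increment_mV: 10
    step_duration_ms: 100
    holding_duration_ms: 50
    sample_interval_ms: 0.1
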