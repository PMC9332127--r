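# Default stoichiometric and device calibration for calorchamber.
# Copy, edit and load with read_calibration(); omitted keys keep the
# package defaults.
protein_factor: 6.25
brouwer:
  cho:   {vco2: 4.170, vo2: -2.965, protein: -0.390}
  fat:   {o2_co2_diff: 1.718, protein: -0.315}
  ee_kj: {vo2: 16.20, vco2: 5.00, protein: -0.95}
weir: {vo2: 3.941, vco2: 1.106, nitrogen: -2.17}
atwater: {cho: 4, protein: 4, fat: 9}
janssen: {ht2_res: 0.401, male: 3.825, age: -0.071, intercept: 5.102}
katch_mcardle: {intercept: 370, slope: 21.6}
# Placeholder counts-to-energy calibration (not an authoritative
# published equation); replace with the study's own coefficients.
accel_calibration:
  pal_intercept: 1.40
  pal_slope: 6.0e-7
  aee_intercept_kcal_d: 300
  aee_slope: 1.5e-3
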