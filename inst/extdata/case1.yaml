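# Case 1: subject A jogging for two hours in a mild environment.
name: case-1
subject:
  age: 25
  height_cm: 177
  weight_kg: 68
  hr_rest: 74
  body_area_cm2: 19199
environment:
  air_temperature_c: 25
  relative_humidity: 0.65
clothing:
  material: cotton
  coverage_rate: 0.7
exercise:
  exercise_type: jogging
  speed_kmh: 7
  eip: 0.6
  duration_min: 120
parameters:
  k_a: 250
  k_sw: 100
  a1: 1.84
  a2: 24.32
  a3: 0.0636
  a4: 0.00321
  a5: 8.32
  a6: 0.38
  dt: 0.1
  fsm_cadence: 1
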