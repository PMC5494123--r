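# Case 2: subject B running fast for half an hour in a warm environment.
name: case-2
subject:
  age: 35
  height_cm: 173
  weight_kg: 74
  hr_rest: 74
  body_area_cm2: 19697
environment:
  air_temperature_c: 28
  relative_humidity: 0.5
clothing:
  material: cotton
  coverage_rate: 0.5
exercise:
  exercise_type: running
  speed_kmh: 12
  eip: 0.8
  duration_min: 30
parameters:
  k_a: 50
  k_sw: 10
  a1: 2.2
  a2: 19.96
  a3: 0.0831
  a4: 0.002526
  a5: 8.32
  a6: 0.38
  dt: 0.1
  fsm_cadence: 0.5
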