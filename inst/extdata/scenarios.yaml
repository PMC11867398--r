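# Screening/chelation scenario table: base case (BC) plus 25 variations.
# Omitted keys fall back to base-case values: lifetime horizon (null),
# cost discounting 4%, effect discounting 1.5%, courses c1=100%/c2=0/c3=0,
# year-2 monitoring blood test with a 60% repeated-course fraction, no
# safety measures, re-exposure after 5 years, 10% re-exposed, screening
# every 5 years thereafter.
scenarios:
  - {label: BC}
  - {label: "1", horizon: 10}
  - {label: "2", horizon: 20}
  - {label: "3", disc_costs: 0.0}
  - {label: "4", disc_effects: 0.0}
  - {label: "5", c2: 0.30}
  - {label: "6", c2: 0.70}
  - {label: "7", c2: 0.30, c3: 0.50}
  - {label: "8", c2: 0.70, c3: 0.50}
  - {label: "9", repeated: 0.30}
  - {label: "10", repeated: 0.80}
  - {label: "11", safety_iron: true}
  - {label: "12", safety_iron: true, iron_supplement_weeks: 8}
  - {label: "13", safety_iron: true, safety_liver: true}
  - {label: "14", reexposure_fraction: 0.01}
  - {label: "15", reexposure_fraction: 0.30}
  - {label: "16", reexposure_fraction: 0.60}
  - {label: "17", reexposure_delay: 10, reexposure_fraction: 0.01, reexposure_interval: 10}
  - {label: "18", reexposure_delay: 10, reexposure_fraction: 0.10, reexposure_interval: 10}
  - {label: "19", reexposure_delay: 10, reexposure_fraction: 0.30, reexposure_interval: 5}
  - {label: "20", reexposure_delay: 10, reexposure_fraction: 0.60, reexposure_interval: 5}
  - {label: "21", reexposure_delay: 20, reexposure_fraction: 0.01, reexposure_interval: 10}
  - {label: "22", reexposure_delay: 20, reexposure_fraction: 0.10, reexposure_interval: 10}
  - {label: "23", reexposure_delay: 20, reexposure_fraction: 0.30, reexposure_interval: 5}
  - {label: "24", reexposure_delay: 20, reexposure_fraction: 0.60, reexposure_interval: 5}
  - {label: "25", reexposure_delay: lifetime, reexposure_fraction: 0.0}
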