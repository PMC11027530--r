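# Example fixed-width layout for the synthetic record dialect.
# 1-based inclusive column positions; every line is exactly `width` chars.
width: 15
year: [1, 4]
gestational_age_weeks: [5, 6]
age_at_death_days: [7, 9]
cause_code: [10, 15]
unknown_gestation: ["99"]
unknown_age: ["999"]
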