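onset_multiplier: 0.469
eligible_age_lo: 45
eligible_age_hi: 69
uptake: 1.0
sensitivity: 0.96
specificity: 0.63
followup: 0
screened_states:
- MD
- SD
- U1
- U2
- U3
- U4
name: hua_county
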