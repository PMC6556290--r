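onset_multiplier: 1.3
eligible_age_lo: 40
eligible_age_hi: 69
uptake: 0.486
sensitivity: 0.96
specificity: 0.63
followup: 10
screened_states:
- MD
- SD
- U1
- U2
- U3
- U4
name: cixian
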