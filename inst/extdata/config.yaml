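groups:
- group_id: atlanta
  species: chimpanzee
  size: 19
- group_id: zurich
  species: orangutan
  size: 9
- group_id: leipzig
  species: orangutan
  size: 7
- group_id: krefeld1
  species: siamang
  size: 4
- group_id: krefeld2
  species: siamang
  size: 4
- group_id: howlettsA
  species: siamang
  size: 5
- group_id: howlettsB
  species: siamang
  size: 5
sessions:
  chimpanzee:
    n_sessions: 24
    session_length_s: 300.0
  orangutan:
    n_sessions: 40
    session_length_s: 900.0
  siamang:
    n_sessions: 40
    session_length_s: 900.0
scan_interval_s: 600.0
scans_per_individual: 35
ethogram:
  chimpanzee:
    chi01: visual
    chi02: visual
    chi03: visual
    chi04: visual
    chi05: visual
    chi06: visual
    chi07: visual
    chi08: visual
    chi09: visual
    chi10: visual
    chi11: visual
    chi12: non_visual
    chi13: non_visual
    chi14: non_visual
    chi15: non_visual
    chi16: non_visual
    chi17: non_visual
    chi18: non_visual
  orangutan:
    ora01: visual
    ora02: visual
    ora03: visual
    ora04: visual
    ora05: visual
    ora06: visual
    ora07: visual
    ora08: visual
    ora09: visual
    ora10: visual
    ora11: non_visual
    ora12: non_visual
    ora13: non_visual
    ora14: non_visual
    ora15: non_visual
    ora16: non_visual
    ora17: non_visual
  siamang:
    sia01: visual
    sia02: visual
    sia03: visual
    sia04: visual
    sia05: visual
    sia06: visual
    sia07: visual
    sia08: visual
    sia09: non_visual
    sia10: non_visual
    sia11: non_visual
    sia12: non_visual
    sia13: non_visual
    sia14: non_visual
age_min: 2.0
age_max: 40.0
mother_min_age_gap: 8.0
affinity_base_logit: -2.0
affinity_sd: 0.8
kin_boost: 1.5
recipient_affinity_scale: 0.5
gesture_rate_per_min:
  chimpanzee: 0.525
  orangutan: 0.0983
  siamang: 0.1333
contexts:
- play
- affiliative
- agonistic
- sexual
modal_context_prob: 0.78
zipf_exponent: 1.0
unknown_rate: 0.05
chain_length_probs:
  '2': 0.5
  '3': 0.3
  '4': 0.2
attention_intercept:
  chimpanzee: 1.6
  orangutan: 2.6
  siamang: 2.0
visual_effect_attention: 1.2
sequence_intercept:
  chimpanzee: -0.4853059
  orangutan: -0.9247059
  siamang: -0.4853059
response_intercept:
  chimpanzee: 0.7354496
  orangutan: 0.4179809
  siamang: 0.7722157
response_seq_center: 0.35
response_att_center: 0.92
dyad_repertoire_intercept:
  chimpanzee: -2.1751973
  orangutan: -1.5998685
  siamang: -0.9895549
beta_age_attention: 0.3
beta_age_attention_visual: 1.06
beta_bond_dyadrep: 0.14
beta_age_seq: -0.29
beta_centrality_seq: -0.21
beta_age_response: 0.17
beta_seq_response: -2.3
beta_attention_response: 1.23
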