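- name: M1-Ind
  level: individual
  family: binomial
  response:
  - repertoire_used
  - repertoire_possible
  full:
  - z_centrality
  - z_age
  - species
  - sex
  - z_effort
  intermediate: ~
  control:
  - sex
  - z_effort
- name: M2-Ind
  level: individual_modality
  family: binomial
  response:
  - attended
  - assessed
  full:
  - modality
  - z_centrality
  - z_age
  - species
  - modality:z_centrality
  - modality:z_age
  - modality:species
  - sex
  intermediate:
  - modality
  - z_centrality
  - z_age
  - species
  - sex
  control:
  - sex
- name: M3-Ind
  level: individual
  family: beta
  response:
  - flexibility
  full:
  - z_centrality
  - z_age
  - species
  - sex
  - z_effort
  intermediate: ~
  control:
  - sex
  - z_effort
- name: M4-Ind
  level: individual
  family: binomial
  response:
  - in_sequence
  - sequence_assessed
  full:
  - z_centrality
  - z_age
  - species
  - sex
  intermediate: ~
  control:
  - sex
- name: M5-Ind
  level: individual
  family: binomial
  response:
  - responded
  - produced
  full:
  - rep_prop
  - att_visual_prop
  - flexibility
  - seq_prop
  - z_centrality
  - z_age
  - species
  - sex
  intermediate:
  - z_centrality
  - z_age
  - species
  - sex
  control:
  - sex
- name: M1-Dyad
  level: dyad
  family: binomial
  response:
  - repertoire_used
  - repertoire_possible
  full:
  - maternal_kin
  - z_bond
  - species
  - z_age_difference
  - sex_combination
  - z_effort
  intermediate: ~
  control:
  - z_age_difference
  - sex_combination
  - z_effort
- name: M2-Dyad
  level: dyad_modality
  family: binomial
  response:
  - attended
  - assessed
  full:
  - modality
  - maternal_kin
  - z_bond
  - species
  - modality:maternal_kin
  - modality:z_bond
  - modality:species
  - z_age_difference
  - sex_combination
  intermediate:
  - modality
  - maternal_kin
  - z_bond
  - species
  - z_age_difference
  - sex_combination
  control:
  - z_age_difference
  - sex_combination
- name: M3-Dyad
  level: dyad
  family: beta
  response:
  - flexibility
  full:
  - maternal_kin
  - z_bond
  - species
  - z_age_difference
  - sex_combination
  - z_effort
  intermediate: ~
  control:
  - z_age_difference
  - sex_combination
  - z_effort
- name: M4-Dyad
  level: dyad
  family: binomial
  response:
  - in_sequence
  - sequence_assessed
  full:
  - maternal_kin
  - z_bond
  - species
  - z_age_difference
  - sex_combination
  intermediate: ~
  control:
  - z_age_difference
  - sex_combination
- name: M5-Dyad
  level: dyad
  family: binomial
  response:
  - responded
  - produced
  full:
  - rep_prop
  - att_visual_prop
  - flexibility
  - seq_prop
  - maternal_kin
  - z_bond
  - species
  - z_age_difference
  - sex_combination
  intermediate:
  - maternal_kin
  - z_bond
  - species
  - z_age_difference
  - sex_combination
  control:
  - z_age_difference
  - sex_combination
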