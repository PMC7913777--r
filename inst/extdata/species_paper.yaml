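# Hydrodynamic properties of the RecO/RecR assembly species.
# vbar_ml_g are the experimentally determined values; vbar_sequence_ml_g
# the sequence-calculated alternatives. eps_230 in M^-1 cm^-1.
species:
  - name: RecO
    mass_kDa: 27.4
    vbar_ml_g: 0.734
    vbar_sequence_ml_g: 0.743
    s_S: 0.8
    eps_230: 155000
  - name: RecO-P15
    mass_kDa: 29.1
    vbar_ml_g: 0.731
    s_S: 0.8
    eps_230: 155000
  - name: RecR2
    mass_kDa: 43.9
    vbar_ml_g: 0.711
    vbar_sequence_ml_g: 0.731
    s_S: 1.2
    eps_230: 106000
  - name: RecR4
    mass_kDa: 87.8
    vbar_ml_g: 0.711
    s_S: 1.7
    eps_230: 212000
  - name: RecR2O
    mass_kDa: 71.3
    vbar_ml_g: 0.720
    s_S: 1.4
    eps_230: 261000
  - name: RecR4O
    mass_kDa: 115.2
    vbar_ml_g: 0.716
    s_S: 1.9
    eps_230: 367000
  - name: RecR4O2
    mass_kDa: 142.6
    vbar_ml_g: 0.720
    s_S: 2.5
    eps_230: 522000
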