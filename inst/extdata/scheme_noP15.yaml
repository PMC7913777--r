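# Assembly network constants describing the RecO/RecR velocity titration
# in the absence of the SSB-Ct peptide (positive cooperativity, K4/K3 = 800).
L_obs: 216000
K2: 10
K3: 500000
K4: 400000000
k_off: 0.01
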