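# Assembly network constants with the SSB-Ct peptide bound to RecO
# (negative cooperativity, K4/K3 = 0.04).
L_obs: 216000
K2: 10
K3: 250000000
K4: 10000000
k_off: 0.01
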