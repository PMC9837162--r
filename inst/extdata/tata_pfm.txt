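# Default TATA-box position probability matrix (width 15).
# Columns 4-11 are the TATAWAWR core (consensus base 0.85, off-consensus 0.05;
# W = A/T at 0.45 each; R = A/G at 0.45 each); columns 1-3 and 12-15 are
# near-uniform flanks (A 0.28, C/G/T 0.24).
A 0.28 0.28 0.28 0.05 0.85 0.05 0.85 0.45 0.85 0.45 0.45 0.28 0.28 0.28 0.28
C 0.24 0.24 0.24 0.05 0.05 0.05 0.05 0.05 0.05 0.05 0.05 0.24 0.24 0.24 0.24
G 0.24 0.24 0.24 0.05 0.05 0.05 0.05 0.05 0.05 0.05 0.45 0.24 0.24 0.24 0.24
T 0.24 0.24 0.24 0.85 0.05 0.85 0.05 0.45 0.05 0.45 0.05 0.24 0.24 0.24 0.24
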