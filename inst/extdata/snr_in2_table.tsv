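# Squared input signal-to-noise ratio per unit air kerma, by beam quality.
# Units: snr_in2 in 1/(mm^2 uGy); kvp in kV.
# Extend this table with additional tabulated beam qualities as needed;
# unknown combinations are never interpolated.
anode_filter	kvp	snr_in2
W/Rh	30	6179
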