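# Published MS2 peak list of the cosmomycin C structural isomer
# ("compound 12", precursor printed as 1173.6); intensities arbitrary.
#id=compound_12
#precursor=1173.6
528.3	70
685.3	60
815.4	75
929.3	85
1059.1	55
1173.6	25
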