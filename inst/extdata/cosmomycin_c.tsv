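# Published MS2 peak list of cosmomycin C (precursor 1173.3); intensities
# arbitrary.
#id=cosmomycin_C
#precursor=1173.3
544.3	70
701.2	60
831.2	75
945.1	85
1059.1	55
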