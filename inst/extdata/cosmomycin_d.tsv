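# Published MS2 peak list of cosmomycin D ([M+H]+ 1189.6); intensities are
# not reported and are arbitrary placeholders on a 0-100 scale.
#id=cosmomycin_D
#precursor=1189.6
544.3	65
595.3	100
701.3	60
831.3	70
945.3	80
1075.5	55
1189.6	30
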