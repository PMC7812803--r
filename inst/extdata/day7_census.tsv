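population	mean	sem	printed
early	451	79.0	TRUE
prepb	389	60.7	TRUE
late_int	5009	871.9	TRUE
late_lo	NA	NA	FALSE
dz	3691	599.4	TRUE
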