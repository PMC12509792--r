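# hu_p: phase-contrast Hounsfield value (relative electron density vs water, per-mille scale)
# re_density: electron density relative to water (computed from composition)
name,density_g_cm3,hu_p,re_density
breast,1.02,,1.01426
adipose,0.95,-83.0,0.95122
fibroglandular,1.04,55.0,1.03059
tumor,1.044,31.0,1.03445
water,1.0,0.0,1.00000
aluminium,2.699,,2.34273
silicon,2.33,,2.09240
gold,19.32,,13.95994
tungsten,19.25,,13.95935
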