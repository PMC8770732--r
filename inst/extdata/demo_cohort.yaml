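# Synthetic cohort generator config (defaults shown; all keys optional).
# The default age sampler reproduces the reference cohort structure:
# five age bands x sex with band weights 24/24/25/25/55 out of 153.
n: 153
age_sampler: {type: table}
sex_offset: 0
# Uncomment to attenuate methylation drift beyond age 80 (old-age
# under-prediction scenario):
# attenuation: {knot: 80, factor: 0.3}
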