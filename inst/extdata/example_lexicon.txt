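# Example drug lexicon: a monotherapy cohort that must not capture the
# combination product.
[target]
Amoxicillin
[synonyms]
amoxicillin
amoxicillin trihydrate
amoxicilline
[exclusions]
amoxicillin and clavulanate potassium
amoxicillin/clavulanic acid
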