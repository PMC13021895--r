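PT	SOC
Urticaria	Skin and subcutaneous tissue disorders
Rash	Skin and subcutaneous tissue disorders
Pruritus	Skin and subcutaneous tissue disorders
Angioedema	Skin and subcutaneous tissue disorders
Anaphylactic shock	Immune system disorders
Type I hypersensitivity	Immune system disorders
Drug-induced liver injury	Hepatobiliary disorders
Cholestatic hepatitis	Hepatobiliary disorders
Diarrhoea	Gastrointestinal disorders
Nausea	Gastrointestinal disorders
Vomiting	Gastrointestinal disorders
Headache	Nervous system disorders
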