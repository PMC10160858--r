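fine_cause,broad_cause
pneumonia,pneumonia
malaria,malaria
diarrhea,diarrhea
severe malnutrition,severe malnutrition
hiv,hiv
other infections,other infections
other,other
meningitis,other infections
typhoid fever,other infections
hepatitis,other infections
sepsis,other infections
measles,other infections
cancer,other
injury,other
road traffic accident,other
drowning,other
congenital malformation,other
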