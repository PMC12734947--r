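# Synthetic demonstration compound library: real formulas/monoisotopic
# masses, retention times invented for the packaged demo method.
name,formula,rt_min
glucose,C6H12O6,4.8
glutamine,C5H10N2O3,3.1
succinate,C4H6O4,8.2
fumarate,C4H4O4,8.6
malate,C4H6O5,7.9
benzoate,C7H6O2,12.4
uracil,C4H4N2O2,2.7
phenylalanine,C9H11NO2,9.5
tryptophan,C11H12N2O2,11.0
pyroglutamate,C5H7NO3,3.6
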