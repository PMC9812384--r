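metabolite,fragment_formula,n_tracer_atoms,pathway_tag
glucose,C33H76NO6Si5,6,glycolysis
g6p,C33H77NO9PSi5,6,glycolysis
3pg,C17H40O7PSi3,3,glycolysis
pep,C11H24O6PSi2,3,glycolysis
pyruvate,C6H12NO3Si,3,glycolysis
lactate,C11H25O3Si2,3,glycolysis
alanine,C11H26NO2Si2,3,amino acid
citrate,C26H55O7Si4,6,TCA
glutamate,C19H42NO4Si3,5,amino acid
fumarate,C12H23O4Si2,4,TCA
malate,C18H39O5Si3,4,TCA
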