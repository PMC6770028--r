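# van der Waals parameters of the Tripos 5.2 force field
# (Clark M., Cramer R.D. III, Van Opdenbosch N., J. Comput. Chem. 10 (1989) 982-1012)
# radius: Angstrom; epsilon: kcal/mol. Mapped onto the package's atom classes.
atom_class,radius,epsilon
sp3-C,1.70,0.107
sp2-C,1.70,0.107
aromatic-C,1.70,0.107
N-cationic,1.55,0.095
N-neutral,1.55,0.095
O,1.52,0.116
S,1.80,0.314
halogen,1.75,0.314
H,1.50,0.042
other,1.70,0.107
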