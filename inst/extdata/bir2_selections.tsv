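# BIR2 residue selections, v1 (1-based UniProt/BIR2 numbering, domain 163-234)
name	residues
domain	163-234
helix1	163-168
helix2	181-186
loop_174_182	174-182
region_192_198	192-198
loop_205_215	205-215
beta1	198-200
beta2	206-208
turn_201_204	201-204
hydrophobic_core	170,173,177,179,184,187,189,198,207,210,216
zn_finger	200,203,220,227
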