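# K48-linked tri-ubiquitin backbone partition, biology (1-based) numbering.
# Moieties: distal (A), middle (B), proximal (C); the flexible C-terminal
# tail residues of each unit are masked out of features and CoG observables.
index_base = 1
domain distal = 1-76
domain middle = 77-152
domain proximal = 153-228
mask = 73-76, 149-152, 225-228
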