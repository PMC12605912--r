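# Thiotepa (C6H12N3PS)
# Hydrogen-suppressed molecular graph: heavy atoms only, bond multiplicity
# collapsed (double/aromatic bonds count as one edge).
# Atom labels are element symbol + canonical atom number.
# 11 vertices, 13 edges.
S1 P2
P2 N3
N3 C4
C4 C5
P2 N6
N6 C7
C7 C8
P2 N9
N9 C10
C10 C11
C5 N3
C8 N6
C11 N9
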