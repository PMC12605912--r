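# Anastrozole (C17H19N5)
# Hydrogen-suppressed molecular graph: heavy atoms only, bond multiplicity
# collapsed (double/aromatic bonds count as one edge).
# Atom labels are element symbol + canonical atom number.
# 22 vertices, 23 edges.
C1 C2
C2 C3
C2 C4
C4 N5
C2 C6
C6 C7
C7 C8
C8 C9
C9 N10
N10 C11
C11 N12
N12 C13
C13 N14
C8 C15
C15 C16
C16 C17
C17 C18
C17 C19
C17 C20
C20 N21
C16 C22
C22 C6
N14 N10
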