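# Letrozole (C17H11N5)
# Hydrogen-suppressed molecular graph: heavy atoms only, bond multiplicity
# collapsed (double/aromatic bonds count as one edge).
# Atom labels are element symbol + canonical atom number.
# 22 vertices, 24 edges.
N1 C2
C2 C3
C3 C4
C4 C5
C5 C6
C6 C7
C7 C8
C6 C9
C9 N10
N10 C11
C11 N12
N12 C13
C13 N14
C9 C15
C15 C16
C16 C17
C17 C18
C18 C19
C19 C20
C18 C21
C21 N22
C8 C3
N14 N10
C20 C15
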