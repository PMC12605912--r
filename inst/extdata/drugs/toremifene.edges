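# Toremifene (C26H28ClNO)
# Hydrogen-suppressed molecular graph: heavy atoms only, bond multiplicity
# collapsed (double/aromatic bonds count as one edge).
# Atom labels are element symbol + canonical atom number.
# 29 vertices, 31 edges.
C1 N2
N2 C3
N2 C4
C4 C5
C5 O6
O6 C7
C7 C8
C8 C9
C9 C10
C10 C11
C11 C12
C10 C13
C13 C14
C14 C15
C15 C16
C16 Cl17
C14 C18
C18 C19
C19 C20
C20 C21
C21 C22
C22 C23
C13 C24
C24 C25
C25 C26
C26 C27
C27 C28
C28 C29
C12 C7
C23 C18
C29 C24
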