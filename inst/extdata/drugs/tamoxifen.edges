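# Tamoxifen (C26H29NO)
# Hydrogen-suppressed molecular graph: heavy atoms only, bond multiplicity
# collapsed (double/aromatic bonds count as one edge).
# Atom labels are element symbol + canonical atom number.
# 28 vertices, 30 edges.
C1 C2
C2 C3
C3 C4
C4 C5
C5 C6
C6 C7
C7 C8
C8 C9
C9 C10
C4 C11
C11 C12
C12 C13
C13 C14
C14 O15
O15 C16
C16 C17
C17 N18
N18 C19
N18 C20
C14 C21
C21 C22
C3 C23
C23 C24
C24 C25
C25 C26
C26 C27
C27 C28
C10 C5
C22 C11
C28 C23
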