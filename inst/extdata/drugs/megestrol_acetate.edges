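# Megestrol Acetate (C24H32O4)
# Hydrogen-suppressed molecular graph: heavy atoms only, bond multiplicity
# collapsed (double/aromatic bonds count as one edge).
# Atom labels are element symbol + canonical atom number.
# 28 vertices, 31 edges.
C1 C2
C2 O3
C2 O4
O4 C5
C5 C6
C6 C7
C6 O8
C5 C9
C9 C10
C10 C11
C11 C12
C12 C13
C13 C14
C14 C15
C14 C16
C16 C17
C17 C18
C18 O19
C18 C20
C20 C21
C21 C22
C22 C23
C22 C24
C24 C25
C25 C26
C26 C27
C27 C28
C27 C5
C27 C11
C24 C12
C22 C16
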