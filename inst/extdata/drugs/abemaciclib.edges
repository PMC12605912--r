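# Abemaciclib (C27H32F2N8)
# Hydrogen-suppressed molecular graph: heavy atoms only, bond multiplicity
# collapsed (double/aromatic bonds count as one edge).
# Atom labels are element symbol + canonical atom number.
# 37 vertices, 41 edges.
C1 C2
C2 N3
N3 C4
C4 C5
C5 N6
N6 C7
C7 C8
C8 C9
C9 C10
C10 C11
C11 N12
N12 C13
C13 N14
N14 C15
C15 C16
C16 F17
C16 C18
C18 C19
C19 C20
C20 C21
C21 F22
C21 C23
C23 N24
N24 C25
C25 C26
C25 N27
N27 C28
C28 C29
C28 C30
N27 C31
C31 C32
C18 N33
C11 N34
N34 C35
N6 C36
C36 C37
C37 N3
C35 C8
N33 C13
C32 C19
C31 C23
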