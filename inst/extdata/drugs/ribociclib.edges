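# Ribociclib (C23H30N8O)
# Hydrogen-suppressed molecular graph: heavy atoms only, bond multiplicity
# collapsed (double/aromatic bonds count as one edge).
# Atom labels are element symbol + canonical atom number.
# 32 vertices, 36 edges.
C1 N2
N2 C3
N2 C4
C4 O5
C4 C6
C6 C7
C7 C8
C8 C9
C9 N10
N10 C11
C11 N12
N12 C13
C13 C14
C14 C15
C15 C16
C16 N17
N17 C18
C18 C19
C19 N20
N20 C21
C21 C22
C16 C23
C23 N24
C11 N25
N25 C26
C26 N27
N27 C28
C28 C29
C29 C30
C30 C31
C31 C32
N27 C6
C32 C28
C26 C8
N24 C13
C22 N17
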