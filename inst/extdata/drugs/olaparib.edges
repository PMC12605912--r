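# Olaparib (C24H23FN4O3)
# Hydrogen-suppressed molecular graph: heavy atoms only, bond multiplicity
# collapsed (double/aromatic bonds count as one edge).
# Atom labels are element symbol + canonical atom number.
# 32 vertices, 36 edges.
# NOTE: exhaustive solving of this transcription yields (beta=4, eta=13,
# xi1=14, xi2=16), which differs from the published invariant table
# (beta=3, eta=8, xi1=10, xi2=23) even though |V| and |E| agree. The
# published drawing is not machine-readable, so the disagreement cannot be
# arbitrated; it is reported by reproduce_report(), never patched.
O1 C2
C2 C3
C3 C4
C4 C5
C5 C6
C6 C7
C7 C8
C8 N9
N9 N10
N10 C11
C11 O12
C11 C13
C13 C14
C14 C15
C15 C16
C16 C17
C17 C18
C6 C19
C19 F20
C19 C21
C2 N22
N22 C23
C23 C24
C24 N25
N25 C26
C26 O27
C26 C28
C28 C29
C29 C30
N25 C31
C31 C32
C21 C3
C32 N22
C18 C8
C30 C28
C18 C13
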