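# Tucatinib (C26H24N8O2)
# Hydrogen-suppressed molecular graph: heavy atoms only, bond multiplicity
# collapsed (double/aromatic bonds count as one edge).
# Atom labels are element symbol + canonical atom number.
# 36 vertices, 41 edges.
C1 C2
C2 C3
C2 C4
C4 O5
O5 C6
C6 N7
C6 N8
N8 C9
C9 C10
C10 C11
C11 C12
C12 N13
N13 C14
C14 N15
N15 C16
C16 N17
N17 C18
C18 C19
C19 C20
C20 C21
C21 O22
O22 C23
C23 C24
C24 C25
C25 N26
N26 N27
N27 C28
C28 N29
N29 C30
C30 C31
C21 C32
C32 C33
C32 C34
C16 C35
C35 C36
N7 C2
C36 C9
C35 C12
C34 C18
C31 C23
C30 N26
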