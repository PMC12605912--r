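drug,n_vertices,n_edges,beta,eta,xi1,xi2
Toremifene,29,31,4,14,14,11
Tucatinib,36,41,3,11,10,26
Ribociclib,32,36,4,14,12,17
Olaparib,32,36,3,8,10,23
Abemaciclib,37,41,3,10,10,27
Anastrozole,22,23,5,12,8,10
Letrozole,22,24,3,12,10,7
Thiotepa,11,13,3,6,6,4
Tamoxifen,28,30,4,14,14,10
Megestrol Acetate,28,31,4,12,9,17
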