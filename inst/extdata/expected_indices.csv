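drug,FRZI1,FRZI2,SRZI,RHM,RF
Toremifene,599,284,651,2618,1316
Tucatinib,499,308,581,2334,1172
Ribociclib,674,334,777,3120,1566
Olaparib,456,272,515,2070,1040
Abemaciclib,522,310,588,2362,1186
Anastrozole,660,258,725,2908,1458
Letrozole,268,168,295,1190,600
Thiotepa,134,92,163,658,332
Tamoxifen,574,274,626,2518,1266
Megestrol Acetate,592,291,685,2749,1379
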