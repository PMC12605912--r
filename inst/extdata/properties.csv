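drug,MV,P,MR,PSA,ST
Toremifene,367.6,49.1,123.7,12,42.1
Tucatinib,339,53.6,135.2,111,57.3
Ribociclib,311.4,48.9,123.4,91,58.2
Olaparib,301.8,46.3,116.9,82,57.8
Abemaciclib,382.3,55.7,140.4,75,45.8
Anastrozole,270.3,35.7,90,78,42.2
Letrozole,234.5,34.5,87.1,78,53.5
Thiotepa,125.8,19.5,49.1,51,77.8
Tamoxifen,356.2,47.1,118.9,12,40.4
Megestrol Acetate,317.4,40.4,102,60,45.3
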