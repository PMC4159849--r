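resA,atomA,resB,atomB,dmax_nm,source
79,CA,83,CA,0.85,synthetic_micelle
83,CA,79,CA,0.85,synthetic_micelle
79,CA,79,CA,0.75,synthetic_micelle
83,CA,83,CA,0.75,synthetic_micelle
87,CB*,83,CA,0.90,synthetic_bicelle
87,CB*,87,CB*,1.00,synthetic_bicelle
75,*,79,CA,1.10,synthetic_bicelle
91,CA,87,CB*,1.05,synthetic_bicelle
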