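assay,concentration_U_per_mL,replicate,I_parallel,I_perpendicular
FA,0,1,1.65327,1
FA,0,2,1.658774,1
FA,1,1,1.646119,1
FA,1,2,1.647483,1
FA,10,1,1.679452,1
FA,10,2,1.660482,1
FA,50,1,1.714595,1
FA,50,2,1.708179,1
FA,100,1,1.732249,1
FA,100,2,1.72337,1
FA,200,1,1.763705,1
FA,200,2,1.768245,1
FA,500,1,1.80848,1
FA,500,2,1.820924,1
FA,1000,1,1.841845,1
FA,1000,2,1.853315,1
FA,2000,1,1.870291,1
FA,2000,2,1.881415,1
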