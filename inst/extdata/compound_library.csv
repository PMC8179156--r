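name,formula,printed_adduct,printed_mz
sulforaphane-glutathione conjugate (SFN-GSH),C16H28N4O7S3,[M+H]+,485.1184
sulforaphane-gamma-glutamylcysteine conjugate (SFN-gEC),C14H25N3O6S3,[M+H]+,428.0979
sulforaphane-cysteine conjugate (SFN-Cys),C9H18N2O3S3,[M+H]+,299.0555
4-methylsulfinyl-n-butyl amine (4MSB-NH2),C5H13NOS,[M+H]+,136.0797
raphanusamic acid (RA),C4H5NO2S2,[M-H]-,161.9683
glutathione (GSH),C10H17N3O6S,[M-H]-,306.0759
sulforaphane (SFN),C6H11NOS2,,
cysteine,C3H7NO2S,,
methionine,C5H11NO2S,,
procysteine (pCys),C4H5NO3S,,
glucoraphanin (4MSB),C12H23NO10S3,,
glucoiberin (3MSP),C11H21NO10S3,,
glucoerucin (4MTB),C12H23NO9S3,,
glucoibarin (7MSH),C15H29NO10S3,,
glucohirsutin (8MSO),C16H31NO10S3,,
sinigrin (allyl GL),C10H17NO9S2,,
gluconasturtiin (PhE),C15H21NO9S2,,
glucobrassicin (I3G),C16H20N2O9S2,,
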