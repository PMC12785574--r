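mz,annotation,ion_class,mean_LEAN,mean_P1,mean_P2,trend,log2fc_lean_p1,log2fc_p2_p1,q_value
536.376,PI frag. (phosphatidylinositol),lipid,3.9e-05,1.8e-05,2.1e-05,Up,1.16,0.24,1.07e-08
241.043,FA frag. (palmitoleic acid),lipid,1.28e-03,9.06e-04,9.24e-04,Up,0.50,0.03,1.55e-05
221.059,Myristic acid frag.,lipid,3.56e-04,5.65e-04,5.30e-04,Down,-0.66,-0.09,7.08e-06
281.253,Oleic/linoleic acid [M-H]-,lipid,2.8e-03,9.6e-03,1.37e-02,Mixed,-1.75,0.52,2.6e-03
283.270,Stearic acid [M-H]-,lipid,4.35e-03,4.21e-03,4.82e-03,Up,0.05,0.20,8.2e-03
404.288,Phospholipid frag.,lipid,4.32e-05,4.15e-05,5.08e-05,Up,0.06,0.29,1.3e-02
115.011,Aspartic acid,lipid,3.18e-04,5.18e-04,4.70e-04,Down,-0.71,-0.14,9.4e-04
465.318,Phosphatidic acid frag.,lipid,9.14e-05,1.36e-04,1.06e-04,Down,-0.57,-0.35,6.3e-03
805.749,PS/PI molecular ion,lipid,2.97e-06,5.89e-06,1.87e-05,Mixed,-0.99,1.67,2.5e-03
806.840,PS/PI adduct,lipid,3.29e-06,5.00e-06,1.24e-05,Mixed,-0.61,1.31,2.6e-03
180.05,Tyrosine [M-H]-,amino_acid,1.45e-03,7.81e-04,8.54e-04,Up,0.890,0.128,3.56e-06
164.07,Phenylalanine [M-H]-,amino_acid,4.30e-03,3.09e-03,3.37e-03,Up,0.476,0.124,6.87e-06
93.05,Small acidic frag.,amino_acid,7.40e-04,1.07e-03,9.13e-04,Down,-0.532,-0.228,2.99e-03
114.03,Acidic AA frag.,amino_acid,9.73e-04,1.60e-03,1.41e-03,Down,-0.717,-0.180,2.67e-03
153.02,AA frag. (aromatic/amide),amino_acid,2.89e-04,3.23e-04,3.79e-04,Mixed,-0.161,0.232,2.67e-03
128.07,Amino acid-related ion,amino_acid,2.46e-03,2.24e-03,1.83e-03,Mixed,0.136,-0.294,4.82e-03
89.03,Lactate [M-H]-,amino_acid,2.38e-03,3.99e-03,3.67e-03,Down,-0.746,-0.120,4.41e-03
209.03,Amino acid/peptidic fragment,amino_acid,1.83e-03,1.70e-03,1.34e-03,Mixed,0.113,-0.345,1.06e-02
40.01,Small frag. (C/O),amino_acid,5.29e-04,5.85e-04,6.59e-04,Mixed,-0.145,0.172,1.18e-02
86.03,AA frag.,amino_acid,2.36e-03,2.89e-03,2.90e-03,Mixed,-0.293,0.0057,1.20e-02
87.01,AA frag.,amino_acid,1.17e-03,1.31e-03,1.41e-03,Mixed,-0.164,0.107,2.50e-02
122.01,Anion (AA/acid),amino_acid,5.33e-04,7.34e-04,6.57e-04,Down,-0.462,-0.159,2.37e-02
42.00,Small fragment,amino_acid,9.74e-03,1.16e-02,1.23e-02,Mixed,-0.253,0.0871,2.74e-02
44.02,Small fragment,amino_acid,5.46e-04,5.71e-04,6.79e-04,Mixed,-0.0661,0.250,1.64e-02
65.01,Amino frag. (amine),amino_acid,4.52e-02,3.90e-02,3.86e-02,Mixed,0.214,-0.0151,1.64e-02
49.01,Small anion,amino_acid,6.27e-04,7.57e-04,5.90e-04,Down,-0.271,-0.359,4.70e-02
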