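gene,phase
Mcm5,G1/S
Pcna,G1/S
Tyms,G1/S
Fen1,G1/S
Mcm2,G1/S
Mcm4,G1/S
Rrm1,G1/S
Ung,G1/S
Gins2,G1/S
Mcm6,G1/S
Cdca7,G1/S
Dtl,G1/S
Prim1,G1/S
Uhrf1,G1/S
Rrm2,S
Cdc45,S
Cdc6,S
Exo1,S
Tipin,S
Dscc1,S
Blm,S
Casp8ap2,S
Usp1,S
Clspn,S
Pola1,S
Chaf1b,S
Rfc2,S
E2f8,S
Hmgb2,G2/M
Cdk1,G2/M
Nusap1,G2/M
Ube2c,G2/M
Birc5,G2/M
Tpx2,G2/M
Top2a,G2/M
Ndc80,G2/M
Cks2,G2/M
Nuf2,G2/M
Cks1b,G2/M
Mki67,G2/M
Cenpf,G2/M
Tacc3,G2/M
Cdc20,M
Ttk,M
Cdc25c,M
Kif2c,M
Rangap1,M
Ncapd2,M
Dlgap5,M
Cdca2,M
Cdca8,M
Ect2,M
Kif23,M
Hmmr,M
Aurka,M
Anln,M
Pttg1,M/G1
Rad21,M/G1
Cdkn3,M/G1
Lbr,M/G1
Anp32e,M/G1
Gas2l3,M/G1
Ctcf,M/G1
Cbx5,M/G1
Nucks1,M/G1
Tmpo,M/G1
Vps25,M/G1
Dynll1,M/G1
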