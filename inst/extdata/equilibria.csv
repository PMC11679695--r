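"id","equation","lgK"
"HSO4","HSO4- = H+ + SO4 2-",-1.94
"H3PO4","H3PO4 = H+ + H2PO4-",-2.04
"H2PO4","H2PO4- = H+ + HPO4 2-",-6.7
"HPO4","HPO4 2- = H+ + PO4 3-",-11.55
"HCO3","HCO3- = H+ + CO3 2-",-10.25
"CaHPO4","Ca2+ + HPO4 2- = CaHPO4 (aq)",1.3
"CaH2PO4","Ca2+ + H2PO4- = CaH2PO4+",0.55
"CaSO4","Ca2+ + SO4 2- = CaSO4 (aq)",4.43
"CaHCO3","Ca2+ + HCO3- = CaHCO3+",1.17
"CaCO3","Ca2+ + CO3 2- = CaCO3 (aq)",3.22
"MgHPO4","Mg2+ + HPO4 2- = MgHPO4 (aq)",1.8
"MgH2PO4","Mg2+ + H2PO4- = MgH2PO4+",0.55
"MgSO4","Mg2+ + SO4 2- = MgSO4 (aq)",2.37
"MgHCO3","Mg2+ + HCO3- = MgHCO3+",0.62
"MgCO3","Mg2+ + CO3 2- = MgCO3 (aq)",1.87
"CaBSA1","Ca2+ + BSA1 = CaBSA1",2.55750720190566
"CaBSA2","Ca2+ + BSA2 = CaBSA2",2.49692964807321
"CaBSA3","Ca2+ + BSA3 = CaBSA3",2.46389298898591
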