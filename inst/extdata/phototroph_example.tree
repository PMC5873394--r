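((Bacteroidetes_1:3000,(Ignavibacteria_1:2561,(GSB_1:1716,(GSB_2:900,GSB_3:900):816):845):439):624,(Alphaproteobacteria_1:3400,((Chloroflexi_1:2950,(Chloroflexi_2:2861,(GNS_1:1986,(GNS_2:900,GNS_3:900):1086):875):89):250,(Sericytochromatia_1:2900,((Melainabacteria_1:1500,Melainabacteria_2:1500):1276,(Gloeobacter_violaceus:2244,(Cyanobacteria_1:1902,(Cyanobacteria_2:1200,Cyanobacteria_3:1200):702):342):532):124):300):200):224);
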