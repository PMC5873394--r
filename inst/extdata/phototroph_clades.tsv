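Crown Cyanobacteria	crown	Gloeobacter_violaceus,Cyanobacteria_1,Cyanobacteria_2,Cyanobacteria_3
Stem Cyanobacteria	stem	Gloeobacter_violaceus,Cyanobacteria_1,Cyanobacteria_2,Cyanobacteria_3
Crown Cyanobacteria excl Gloeobacter	crown	Cyanobacteria_1,Cyanobacteria_2,Cyanobacteria_3
Crown GNS	crown	GNS_1,GNS_2,GNS_3
Stem GNS	stem	GNS_1,GNS_2,GNS_3
Crown GSB	crown	GSB_1,GSB_2,GSB_3
Stem GSB	stem	GSB_1,GSB_2,GSB_3
Chloroflexi	crown	Chloroflexi_1,Chloroflexi_2,GNS_1,GNS_2,GNS_3
CyanoMelaina	crown	Melainabacteria_1,Melainabacteria_2,Gloeobacter_violaceus,Cyanobacteria_1,Cyanobacteria_2,Cyanobacteria_3
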