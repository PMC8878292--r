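"smiles","target","ic50_nM","source","assay","mw","logp","ro5_violations"
"c1ccc2nc(F)cc([N+](=O)[O-])c2c1","EGFR",594.264838106501,"SYNTH","biochemical single-protein assay EGFR",209,-0.1,0
"C(#Cc1ccc(I)cc1)c1ccc(CC)cc1","EGFR",509.1060879652,"SYNTH","biochemical single-protein assay EGFR",249.5,4.25,0
"c1cc(Br)cc(C)c1","EGFR",198406.497541502,"SYNTH","biochemical single-protein assay EGFR",128,2,0
"c1ccc(-c2ccc(CCO)cc2)cc1I","EGFR",7.65057299237256,"SYNTH","biochemical single-protein assay EGFR",236,3.1,0
"c1nc([N+](=O)[O-])cc(C(=O)N)c1","EGFR",238.434058521474,"SYNTH","biochemical single-protein assay EGFR",162,-2.4,0
"C(#Cc1ccc(N)cc1)c1ccc(OC(F)(F)F)cc1","EGFR",1917.95079667616,"SYNTH","biochemical single-protein assay EGFR",330,3.2,0
"C(#Cc1ccc([N+](=O)[O-])cc1)c1ccc(CC)cc1","EGFR",1320.73591241167,"SYNTH","biochemical single-protein assay EGFR",256.5,2.05,0
"O=C(c1ccc([N+](=O)[O-])cc1)Nc1ccc(SC)cc1","EGFR",104682.511700667,"SYNTH","biochemical single-protein assay EGFR",270,0.5,0
"O=C(c1ccc(C(=O)C)cc1)Nc1ccc(CO)cc1.Cl","EGFR",2218.54949626174,"SYNTH","biochemical single-protein assay EGFR",303.5,1.65,0
"c1nc(SC)cc([N+](=O)[O-])c1.Cl","EGFR",2974.45838639996,"SYNTH","biochemical single-protein assay EGFR",182,-0.6,0
"c1ccc(-c2ccc(CCO)cc2)cc1OC","EGFR",4.99946873642685,"SYNTH","biochemical single-protein assay EGFR",229.5,2.45,0
"O=C(Nc1ccc(OCC)cc1)Nc1ccc(Cl)cc1","EGFR",4878.75273509569,"SYNTH","biochemical single-protein assay EGFR",290,1.4,0
"c1nc(CCO)cc(N(C)C)c1","EGFR",8335.51269604527,"SYNTH","biochemical single-protein assay EGFR",162,0.3,0
"c1ccc2nc(CN)cc(N)c2c1","EGFR",1424.36696762116,"SYNTH","biochemical single-protein assay EGFR",175.5,0.55,0
"c1cc([N+](=O)[O-])cc(C(=O)O)c1","EGFR",1649.33107258495,"SYNTH","biochemical single-protein assay EGFR",162,-1.5,0
"c1cc(SC)ccc1Nc1ncnc(C)c1.O","EGFR",62922.7940160921,"SYNTH","biochemical single-protein assay EGFR",229.5,0.65,0
"c1nc(C(=O)O)nc(OC(F)(F)F)c1","EGFR",1833.66775052659,"SYNTH","biochemical single-protein assay EGFR",249,-1,0
"c1nc(OC)cc(Br)c1","MET",15897.0646524129,"SYNTH","biochemical single-protein assay MET",141.5,0.45,0
"C(#Cc1ccc(S)cc1)c1ccc(SC)cc1","MET",325.812216484362,"SYNTH","biochemical single-protein assay MET",229.5,4.25,0
"c1ccc(-c2ccc(CCO)cc2)cc1I","MET",0.337707944624215,"SYNTH","biochemical single-protein assay MET",236,3.1,0
"c1nc([N+](=O)[O-])cc(C(=O)N)c1","MET",115.879140766284,"SYNTH","biochemical single-protein assay MET",162,-2.4,0
"C(#Cc1ccc(N)cc1)c1ccc(OC(F)(F)F)cc1","MET",52.3518475502766,"SYNTH","biochemical single-protein assay MET",330,3.2,0
"c1cc(OC(F)(F)F)ccc1Nc1ncnc(I)c1","MET",1056.87042117415,"SYNTH","biochemical single-protein assay MET",336.5,1.15,0
"C(#Cc1ccc([N+](=O)[O-])cc1)c1ccc(CC)cc1","MET",35.8093794820349,"SYNTH","biochemical single-protein assay MET",256.5,2.05,0
"O=C(c1ccc([N+](=O)[O-])cc1)Nc1ccc(SC)cc1.Cl","MET",1387.78573911104,"SYNTH","biochemical single-protein assay MET",303.5,0.75,0
"O=C(Nc1ccc(C(=O)C)cc1)Nc1ccccc1","MET",1750.49118772887,"SYNTH","biochemical single-protein assay MET",256.5,1.15,0
"O=C(c1ccc(C(=O)C)cc1)Nc1ccc(CO)cc1.O","MET",437.898087864834,"SYNTH","biochemical single-protein assay MET",283.5,0.75,0
"c1nc(SC)cc([N+](=O)[O-])c1","MET",193.940628478822,"SYNTH","biochemical single-protein assay MET",148.5,-0.85,0
"c1ccc(-c2ccc(CCO)cc2)cc1OC.OC(=O)C","MET",2.06655069983166,"SYNTH","biochemical single-protein assay MET",283.5,1.65,0
"O=C(Nc1ccc(OCC)cc1)Nc1ccc(Cl)cc1","MET",271.449657476991,"SYNTH","biochemical single-protein assay MET",290,1.4,0
"c1nc(CCO)cc(N(C)C)c1","MET",119.284318060351,"SYNTH","biochemical single-protein assay MET",162,0.3,0
"c1ccc(-c2ccc(CCC)cc2)cc1Br","MET",105.795042808447,"SYNTH","biochemical single-protein assay MET",236,4,0
"c1ccc2nc(CN)cc(N)c2c1.Cl","MET",6.18039795544043,"SYNTH","biochemical single-protein assay MET",209,0.8,0
"c1cc(SC)ccc1Nc1ncnc(C)c1","MET",1535.15029414991,"SYNTH","biochemical single-protein assay MET",216,1.3,0
"c1nc(OC)cc(Br)c1","ROS1",1551.59951625871,"SYNTH","biochemical single-protein assay ROS1",141.5,0.45,0
"O=C(Nc1ccc(CCO)cc1)Nc1ccc(SC)cc1","ROS1",39982.6376308993,"SYNTH","biochemical single-protein assay ROS1",283.5,1.65,0
"C(#Cc1ccc(S)cc1)c1ccc(SC)cc1","ROS1",7555.10799370842,"SYNTH","biochemical single-protein assay ROS1",229.5,4.25,0
"c1cc([N+](=O)[O-])nn1SC","ROS1",2409.06204202468,"SYNTH","biochemical single-protein assay ROS1",135,-2,0
"c1ccc(-c2ccc(CCO)cc2)cc1I","ROS1",54.0768791796414,"SYNTH","biochemical single-protein assay ROS1",236,3.1,0
"c1nc([N+](=O)[O-])cc(C(=O)N)c1","ROS1",494.17199873037,"SYNTH","biochemical single-protein assay ROS1",162,-2.4,0
"C(#Cc1ccc(N)cc1)c1ccc(OC(F)(F)F)cc1","ROS1",43.1841461401968,"SYNTH","biochemical single-protein assay ROS1",330,3.2,0
"O=C(c1ccc([N+](=O)[O-])cc1)Nc1ccc(SC)cc1.OC(=O)C","ROS1",65330.320275836,"SYNTH","biochemical single-protein assay ROS1",324,-0.3,0
"O=C(c1ccc(C(=O)C)cc1)Nc1ccc(CO)cc1","ROS1",494.59153865888,"SYNTH","biochemical single-protein assay ROS1",270,1.4,0
"c1ccc(-c2ccc(CCO)cc2)cc1OC","ROS1",18.9648311558811,"SYNTH","biochemical single-protein assay ROS1",229.5,2.45,0
"c1nc(CCO)cc(N(C)C)c1","ROS1",4776.25771696895,"SYNTH","biochemical single-protein assay ROS1",162,0.3,0
"c1cc([N+](=O)[O-])cc(C(=O)O)c1","ROS1",10898.5875636601,"SYNTH","biochemical single-protein assay ROS1",162,-1.5,0
"c1cc(SC)ccc1Nc1ncnc(C)c1","ROS1",74480.1362400244,"SYNTH","biochemical single-protein assay ROS1",216,1.3,0
"c1nc(C(=O)O)nc(OC(F)(F)F)c1","ROS1",56.1425857443406,"SYNTH","biochemical single-protein assay ROS1",249,-1,0
"c1ccc(-c2ccc(CCO)cc2)cc1I","ROS1",54.0768791796414,"SYNTH","biochemical single-protein assay ROS1",236,3.1,0
"c1cc([N+](=O)[O-])nn1SC","ROS1",2409.06204202468,"SYNTH","biochemical single-protein assay ROS1",135,-2,0
"c1ccc(-c2ccc(CCC)cc2)cc1Br","MET",175.712212987352,"SYNTH","biochemical single-protein assay MET",236,4,0
"c1cc([N+](=O)[O-])cc(C(=O)O)c1","EGFR",9336.61258843934,"SYNTH","biochemical single-protein assay EGFR",162,-1.5,0
"c1nc(OC)cc(Br)c1","ROS1",4752.65042125693,"SYNTH","biochemical single-protein assay ROS1",141.5,0.45,0
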