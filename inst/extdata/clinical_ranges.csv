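variable_id,sex,min,max,source
P0,M,90,120,blood pressure guideline
P1,M,60,80,blood pressure guideline
DP0,M,20,60,blood pressure guideline
DP1,M,70,93,blood pressure guideline
T0,M,35.5,37,temperature reference
T1,M,35.4,37.8,temperature reference
T2,M,,37.5,temperature reference
B0,M,,,data range
B1,M,1.6,,stature reference
DB1,M,18,27,BMI reference
B2,M,,90,waist circumference reference
B3,M,,,data range
B4,M,24,,arm circumference reference
B6,M,,,data range
B7,M,,,data range
B8,M,,,data range
B9,M,,,data range
DB2,M,,0.95,waist-hip ratio reference
DB3,M,,0.54,waist-height ratio reference
B10,M,,,data range
B11,M,,,data range
DB4,M,,,data range
DB5,M,,,data range
M1,M,40,150,lipid panel reference
M2,M,,200,lipid panel reference
M3,M,40,90,lipid panel reference
M4,M,,116,lipid panel reference
M5,M,70,100,fasting glucose reference
M6,M,2.6,24.9,insulin reference
M7,M,10,50,urea reference
M8,M,9,23,BUN reference
M9,M,,6.8,uric acid reference
M10,M,0.8,1.5,creatinine reference
M12,M,,5.7,HbA1c reference
M13,M,0,0.65,CRP reference
M17,M,8.8,10.7,calcium reference
M18,M,2.3,6,phosphorus reference
M19,M,0.2,1.3,bilirubin reference
M20,M,0,0.3,bilirubin reference
M21,M,0.09,0.65,bilirubin reference
M22,M,5,35,AST reference
DM0,M,,1.7,HOMA-IR reference
DM1,M,90,120,eGFR reference
DM2,M,,,data range
DM3,M,,,data range
DM4,M,,,data range
H0,M,3.5,12,leukocyte reference
H1,M,1.9,8,neutrophil reference
DH1,M,40,70,neutrophil reference
H2,M,,,data range
H3,M,1.5,3,lymphocyte reference
DH2,M,20,40,lymphocyte reference
H4,M,0.16,1,monocyte reference
DH3,M,0,10,monocyte reference
H5,M,0,0.8,eosinophil reference
DH4,M,0,5,eosinophil reference
H6,M,0,0.2,basophil reference
DH5,M,0,1,basophil reference
H7,M,4.6,6.2,red cell reference
H8,M,14.9,18.7,hemoglobin reference
H9,M,40,54,hematocrit reference
H10,M,76,100,red cell indices reference
H11,M,27.5,33.2,red cell indices reference
H12,M,32.5,35.2,red cell indices reference
H13,M,11.4,13.5,red cell indices reference
H14,M,147,384,platelet reference
H15,M,6,13.2,platelet reference
P0,F,90,120,blood pressure guideline
P1,F,60,80,blood pressure guideline
DP0,F,20,60,blood pressure guideline
DP1,F,70,93,blood pressure guideline
T0,F,35.5,37,temperature reference
T1,F,35.4,37.8,temperature reference
T2,F,,37.5,temperature reference
B0,F,,,data range
B1,F,,,data range
DB1,F,18,27,BMI reference
B2,F,,80,waist circumference reference
B3,F,,,data range
B4,F,24,,arm circumference reference
B6,F,,,data range
B7,F,,,data range
B8,F,,,data range
B9,F,,,data range
DB2,F,,0.8,waist-hip ratio reference
DB3,F,,0.54,waist-height ratio reference
B10,F,,,data range
B11,F,,,data range
DB4,F,,,data range
DB5,F,,,data range
M1,F,40,150,lipid panel reference
M2,F,,200,lipid panel reference
M3,F,50,90,lipid panel reference
M4,F,,116,lipid panel reference
M5,F,70,100,fasting glucose reference
M6,F,2.6,24.9,insulin reference
M7,F,10,50,urea reference
M8,F,9,23,BUN reference
M9,F,,6.8,uric acid reference
M10,F,0.5,1.1,creatinine reference
M12,F,,5.7,HbA1c reference
M13,F,0,0.65,CRP reference
M17,F,8.8,10.7,calcium reference
M18,F,2.3,6,phosphorus reference
M19,F,0.2,1.3,bilirubin reference
M20,F,0,0.3,bilirubin reference
M21,F,0.09,0.65,bilirubin reference
M22,F,5,35,AST reference
DM0,F,,1.8,HOMA-IR reference
DM1,F,90,120,eGFR reference
DM2,F,,,data range
DM3,F,,,data range
DM4,F,,,data range
H0,F,3.5,12,leukocyte reference
H1,F,1.9,8,neutrophil reference
DH1,F,40,70,neutrophil reference
H2,F,,,data range
H3,F,1.5,3,lymphocyte reference
DH2,F,20,40,lymphocyte reference
H4,F,0.16,1,monocyte reference
DH3,F,0,10,monocyte reference
H5,F,0,0.8,eosinophil reference
DH4,F,0,5,eosinophil reference
H6,F,0,0.2,basophil reference
DH5,F,0,1,basophil reference
H7,F,4.2,5.4,red cell reference
H8,F,12,16,hemoglobin reference
H9,F,36,48,hematocrit reference
H10,F,76,100,red cell indices reference
H11,F,27.5,33.2,red cell indices reference
H12,F,32.5,35.2,red cell indices reference
H13,F,11.4,13.5,red cell indices reference
H14,F,147,384,platelet reference
H15,F,6,13.2,platelet reference
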