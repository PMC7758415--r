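flavor_class,accession,evolution_type,soluble_solids,fructose,glucose,citric_acid,malic_acid,sugar_acid_ratio
I,PL11,Large-fruited,6.03,1290.00,838.50,251.33,144.17,5.38
I,PC4,Cherry,8.17,1801.20,1023.15,451.92,266.03,3.93
I,PC2,Cherry,7.23,2148.80,1220.60,267.21,157.29,7.94
I,RL2,Large-fruited,4.77,1376.67,840.00,332.82,235.60,3.90
I,PC8,Cherry,6.80,2391.07,1358.22,243.89,143.57,9.68
I,RL35,Large-fruited,5.23,1465.17,894.00,178.67,126.48,7.73
I,RC6,Cherry,7.13,1420.83,955.83,264.18,57.35,7.39
I,RC10,Cherry,9.63,2145.00,1443.00,461.72,100.23,6.38
I,PL13,Large-fruited,4.97,1120.00,728.00,278.40,159.70,4.22
I,PC7,Cherry,7.07,1716.93,975.28,347.91,204.80,4.87
II,RL33,Large-fruited,4.30,1307.83,798.00,255.74,181.04,4.82
II,RL19,Large-fruited,4.27,1327.50,810.00,253.99,179.80,4.93
II,PL7,Large-fruited,4.37,1100.00,715.00,344.13,197.40,3.35
II,PL9,Large-fruited,6.10,1530.00,994.50,214.60,123.10,7.48
II,RC8,Cherry,5.53,1475.83,992.83,359.38,78.02,5.64
II,PL4,Large-fruited,4.43,1250.00,812.50,421.47,241.76,3.11
II,PC3,Cherry,8.67,2096.13,1190.68,451.92,266.03,4.58
II,RC9,Cherry,9.23,2374.17,1597.17,309.40,67.17,10.55
II,PC1,Cherry,7.17,2085.60,1184.70,310.25,182.63,6.64
II,RL20,Large-fruited,3.90,1140.67,696.00,268.01,189.72,4.01
II,RL12,Large-fruited,6.30,1288.17,786.00,280.27,198.40,4.33
II,RL36,Large-fruited,4.07,1278.33,780.00,253.99,179.80,4.74
II,PC6,Cherry,11.43,2401.60,1364.20,243.89,143.57,9.72
II,RC1,Cherry,5.20,1237.50,832.50,409.36,88.87,4.15
II,RL28,Large-fruited,5.37,1602.83,978.00,544.77,385.64,2.77
II,RL26,Large-fruited,5.53,1091.50,666.00,282.02,199.64,3.65
II,RC7,Cherry,9.97,2090.00,1406.00,264.18,57.35,10.87
II,PL6,Large-fruited,6.00,1200.00,780.00,278.40,159.70,4.52
II,RC5,Cherry,6.80,1714.17,1153.17,390.32,84.73,6.04
II,RL8,Large-fruited,4.67,1111.17,678.00,224.21,158.72,4.67
III,RL23,Large-fruited,6.10,1091.50,666.00,210.20,148.80,4.90
III,RC4,Cherry,7.03,1815.00,1221.00,514.08,111.60,4.85
III,RL25,Large-fruited,6.97,1593.00,972.00,259.25,183.52,5.79
III,RL27,Large-fruited,5.93,1396.33,852.00,120.87,85.56,10.89
III,RL37,Large-fruited,6.40,1229.17,750.00,194.44,137.64,5.96
III,RL1,Large-fruited,5.03,1337.33,816.00,201.44,142.60,6.26
III,PL2,Large-fruited,5.47,1270.00,825.50,280.33,160.81,4.75
III,PL1,Large-fruited,6.37,1560.00,1014.00,320.93,184.09,5.10
III,RL3,Large-fruited,4.53,1337.33,816.00,283.77,200.88,4.44
III,RL9,Large-fruited,5.63,1307.83,798.00,218.96,155.00,5.63
III,RC2,Cherry,8.03,1925.00,1295.00,254.66,55.28,10.39
III,RL13,Large-fruited,6.23,1317.67,804.00,252.24,178.56,4.92
III,RL31,Large-fruited,6.80,1219.33,744.00,178.67,126.48,6.43
III,RL14,Large-fruited,4.43,1071.83,654.00,197.94,140.12,5.11
III,PL12,Large-fruited,6.33,1650.00,1072.50,286.13,164.13,6.05
III,PL3,Large-fruited,5.67,1660.00,1079.00,274.53,157.48,6.34
III,PL15,Large-fruited,5.67,1440.00,936.00,351.87,201.84,4.29
III,RL16,Large-fruited,9.93,1760.17,1074.00,252.24,178.56,6.58
III,RL6,Large-fruited,5.30,1032.50,630.00,234.72,166.16,4.15
III,RC11,Cherry,6.73,1613.33,1085.33,490.28,106.43,4.52
III,RL21,Large-fruited,5.73,1671.67,1020.00,436.17,308.76,3.61
III,PC5,Cherry,6.67,2212.00,1256.50,245.69,144.63,8.89
III,RL10,Large-fruited,3.67,1121.00,684.00,196.19,138.88,5.39
III,PL5,Large-fruited,5.03,1220.00,793.00,288.07,165.24,4.44
III,PL14,Large-fruited,3.83,1470.00,955.50,264.87,151.93,5.82
III,RC3,Cherry,6.07,1585.83,1066.83,323.68,70.27,6.73
III,PL8,Large-fruited,5.37,1050.00,682.50,255.20,146.39,4.31
III,RL24,Large-fruited,6.10,1091.50,666.00,199.69,141.36,5.15
IV,RL7,Large-fruited,4.27,1366.83,834.00,199.69,141.36,6.45
IV,RL15,Large-fruited,6.07,1268.50,774.00,183.93,130.20,6.50
IV,RL4,Large-fruited,5.53,1121.00,684.00,294.28,208.32,3.59
IV,PL10,Large-fruited,6.67,1850.00,1202.50,187.53,107.57,10.34
IV,RL17,Large-fruited,4.40,1081.67,660.00,215.46,152.52,4.73
IV,RL22,Large-fruited,5.97,1347.17,822.00,271.51,192.20,4.68
IV,RL32,Large-fruited,5.63,1396.33,852.00,301.29,213.28,4.37
IV,RL5,Large-fruited,4.40,1130.83,690.00,143.64,101.68,7.42
IV,RL29,Large-fruited,5.17,1248.83,762.00,196.19,138.88,6.00
IV,RL11,Large-fruited,4.57,1268.50,774.00,203.19,143.84,5.89
IV,RL30,Large-fruited,6.50,1150.50,702.00,206.70,146.32,5.25
IV,RL18,Large-fruited,5.40,1022.67,624.00,264.50,187.24,3.65
IV,RL34,Large-fruited,4.97,914.50,558.00,262.75,186.00,3.28
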