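transect,quadrat,position,N,dN,lagged_dN,Ii,p_printed
T07,Q25,25,5,1.25,3.00,2.42,<0.01
T09,Q07,7,7,1.75,1.75,1.78,0.010
T09,Q25,25,8,2.00,1.75,2.47,<0.01
T12,Q11,11,13,3.25,2.12,2.02,<0.01
T12,Q12,12,14,3.50,2.00,1.94,<0.01
T13,Q16,16,12,3.00,2.50,1.75,0.01
T13,Q17,17,10,2.50,3.25,2.10,<0.01
T13,Q18,18,14,3.50,2.62,2.86,<0.01
T16,Q01,1,12,3.00,2.00,2.02,0.03
T16,Q02,2,8,2.00,3.00,2.02,<0.01
T16,Q03,3,12,3.00,2.00,2.02,<0.01
T18,Q01,1,4,1.00,1.00,2.91,<0.01
T20,Q16,16,10,2.50,2.12,1.67,0.02
T20,Q21,21,10,2.50,2.12,1.67,0.02
T21,Q24,24,9,2.25,1.12,1.46,0.04
T23,Q01,1,8,2.00,1.75,6.46,<0.01
T23,Q02,2,7,1.75,1.62,4.72,<0.01
T23,Q03,3,5,1.25,1.12,1.34,0.048
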