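donor_id,compound,readout,replicate,value,cells_per_well
D01,BASELINE,prolif_d6,1,335.9,1e+05
D01,BASELINE,prolif_d6,2,349.7,1e+05
D01,BASELINE,prolif_d6,3,681.2,1e+05
D01,BASELINE,prolif_d6,4,391.3,1e+05
D01,BASELINE,prolif_d6,5,707.6,1e+05
D01,BASELINE,prolif_d6,6,589.1,1e+05
D01,KLH,prolif_d6,1,79712,1e+05
D01,KLH,prolif_d6,2,73168.2,1e+05
D01,KLH,prolif_d6,3,85835.2,1e+05
D01,KLH,prolif_d6,4,72427.9,1e+05
D01,KLH,prolif_d6,5,93676.7,1e+05
D01,KLH,prolif_d6,6,66517.1,1e+05
D01,infliximab,prolif_d6,1,5522.1,1e+05
D01,infliximab,prolif_d6,2,13056.2,1e+05
D01,infliximab,prolif_d6,3,9593.7,1e+05
D01,infliximab,prolif_d6,4,4832.8,1e+05
D01,infliximab,prolif_d6,5,10580.5,1e+05
D01,infliximab,prolif_d6,6,7886.7,1e+05
D01,BASELINE,prolif_d8,1,529.7,1e+05
D01,BASELINE,prolif_d8,2,615.1,1e+05
D01,BASELINE,prolif_d8,3,470.7,1e+05
D01,BASELINE,prolif_d8,4,403.4,1e+05
D01,BASELINE,prolif_d8,5,570,1e+05
D01,BASELINE,prolif_d8,6,521.3,1e+05
D01,KLH,prolif_d8,1,119983.4,1e+05
D01,KLH,prolif_d8,2,87999.2,1e+05
D01,KLH,prolif_d8,3,90363.5,1e+05
D01,KLH,prolif_d8,4,128720.8,1e+05
D01,KLH,prolif_d8,5,119443.9,1e+05
D01,KLH,prolif_d8,6,81097.7,1e+05
D01,infliximab,prolif_d8,1,13130.4,1e+05
D01,infliximab,prolif_d8,2,7596.4,1e+05
D01,infliximab,prolif_d8,3,4715.8,1e+05
D01,infliximab,prolif_d8,4,9992.5,1e+05
D01,infliximab,prolif_d8,5,5790.5,1e+05
D01,infliximab,prolif_d8,6,5706.8,1e+05
D01,BASELINE,elispot,1,8,5e+05
D01,BASELINE,elispot,2,4,5e+05
D01,BASELINE,elispot,3,3,5e+05
D01,KLH,elispot,1,573,5e+05
D01,KLH,elispot,2,467,5e+05
D01,KLH,elispot,3,534,5e+05
D01,infliximab,elispot,1,50,5e+05
D01,infliximab,elispot,2,42,5e+05
D01,infliximab,elispot,3,63,5e+05
D02,BASELINE,prolif_d6,1,651.6,1e+05
D02,BASELINE,prolif_d6,2,721.7,1e+05
D02,BASELINE,prolif_d6,3,584.8,1e+05
D02,BASELINE,prolif_d6,4,605.8,1e+05
D02,BASELINE,prolif_d6,5,482,1e+05
D02,BASELINE,prolif_d6,6,420.3,1e+05
D02,KLH,prolif_d6,1,89753.7,1e+05
D02,KLH,prolif_d6,2,80733.3,1e+05
D02,KLH,prolif_d6,3,84426.5,1e+05
D02,KLH,prolif_d6,4,34648,1e+05
D02,KLH,prolif_d6,5,89592.8,1e+05
D02,KLH,prolif_d6,6,92946.6,1e+05
D02,infliximab,prolif_d6,1,332.4,1e+05
D02,infliximab,prolif_d6,2,576.7,1e+05
D02,infliximab,prolif_d6,3,333.9,1e+05
D02,infliximab,prolif_d6,4,463.1,1e+05
D02,infliximab,prolif_d6,5,485.6,1e+05
D02,infliximab,prolif_d6,6,535.1,1e+05
D02,BASELINE,prolif_d8,1,559.1,1e+05
D02,BASELINE,prolif_d8,2,599.2,1e+05
D02,BASELINE,prolif_d8,3,385.6,1e+05
D02,BASELINE,prolif_d8,4,623.6,1e+05
D02,BASELINE,prolif_d8,5,780.6,1e+05
D02,BASELINE,prolif_d8,6,758.1,1e+05
D02,KLH,prolif_d8,1,84371.1,1e+05
D02,KLH,prolif_d8,2,83823,1e+05
D02,KLH,prolif_d8,3,103632.4,1e+05
D02,KLH,prolif_d8,4,78354.9,1e+05
D02,KLH,prolif_d8,5,76776,1e+05
D02,KLH,prolif_d8,6,102902.4,1e+05
D02,infliximab,prolif_d8,1,413.4,1e+05
D02,infliximab,prolif_d8,2,908.5,1e+05
D02,infliximab,prolif_d8,3,466.3,1e+05
D02,infliximab,prolif_d8,4,451.8,1e+05
D02,infliximab,prolif_d8,5,480.6,1e+05
D02,infliximab,prolif_d8,6,436.9,1e+05
D02,BASELINE,elispot,1,12,5e+05
D02,BASELINE,elispot,2,7,5e+05
D02,BASELINE,elispot,3,9,5e+05
D02,KLH,elispot,1,434,5e+05
D02,KLH,elispot,2,413,5e+05
D02,KLH,elispot,3,406,5e+05
D02,infliximab,elispot,1,3,5e+05
D02,infliximab,elispot,2,7,5e+05
D02,infliximab,elispot,3,3,5e+05
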