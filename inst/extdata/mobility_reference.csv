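protein,comparison,strain,d_static,d_static_sd,d_mobile,d_mobile_sd,static_pct,static_pct_sd,mobile_pct,mobile_pct_sd,dwell_s,dwell_s_sd
DgcK,ydaK,WT,0.079,0.001,0.657,0.081,69.7,2.1,30.3,2.1,0.049,0.002
DgcK,ydaK,dydaK,0.079,0.001,0.657,0.081,56.7,4.7,43.3,4.7,0.041,0.002
DgcK,ydaK,EtOH4pct,0.079,0.001,0.657,0.081,79.0,4.4,21.0,4.4,0.058,0.006
DgcK,ydaK,Pxyl-ydaKLMN,0.079,0.001,0.657,0.081,90.7,4.5,9.3,4.5,0.067,0.001
DgcK,dgrA,WT,0.075,0.004,0.383,0.040,70.3,10.0,29.7,10.0,0.070,0.002
DgcK,dgrA,ddgrA,0.075,0.004,0.383,0.040,18.3,1.5,81.7,1.5,0.035,0.002
CdaA,ydaK,WT,0.048,0.00021,0.680,0.0043,55.00,0.17,45.00,0.17,NA,NA
CdaA,ydaK,dydaK,0.048,0.00021,0.680,0.0043,57.0,0.17,43.0,0.17,NA,NA
CdaA,dgrA,WT,0.040,0.00017,0.370,0.003,59.00,0.23,41.00,0.23,NA,NA
CdaA,dgrA,ddgrA,0.040,0.00017,0.370,0.003,61.0,0.23,39.0,0.23,NA,NA
DgcP,dgrA,WT,0.07,0.0003,0.57,0.001,65.0,4.8,35.0,4.8,0.048,0.004
DgcP,dgrA,ddgrA,0.072,0.0003,0.57,0.001,31.3,6.4,68.7,6.4,0.030,0.002
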