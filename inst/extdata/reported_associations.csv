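rsid,trait,model,beta,se,p
rs10773003,TG,1,-0.04,0.05,0.383
rs10773003,TC,1,-0.02,0.05,0.721
rs10773003,HDL,1,0.00,0.05,0.990
rs10773003,LDL,1,-0.02,0.05,0.742
rs10773003,VLDL,1,-0.04,0.05,0.383
rs10773003,TG,2,-0.05,0.05,0.312
rs10773003,TC,2,0.00,0.05,0.921
rs10773003,HDL,2,0.01,0.05,0.796
rs10773003,LDL,2,-0.01,0.05,0.909
rs10773003,VLDL,2,-0.05,0.05,0.312
rs174546,TG,1,0.13,0.04,0.004
rs174546,TC,1,-0.03,0.04,0.471
rs174546,HDL,1,-0.11,0.04,0.010
rs174546,LDL,1,-0.06,0.04,0.181
rs174546,VLDL,1,0.13,0.04,0.004
rs174546,TG,2,0.11,0.04,0.014
rs174546,TC,2,-0.06,0.05,0.191
rs174546,HDL,2,-0.10,0.04,0.025
rs174546,LDL,2,-0.09,0.04,0.036
rs174546,VLDL,2,0.11,0.04,0.014
rs17482753,TG,1,0.19,0.06,0.001
rs17482753,TC,1,0.05,0.06,0.418
rs17482753,HDL,1,-0.13,0.06,0.018
rs17482753,LDL,1,0.02,0.06,0.756
rs17482753,VLDL,1,0.19,0.06,0.001
rs17482753,TG,2,0.21,0.06,0.0005
rs17482753,TC,2,0.06,0.06,0.332
rs17482753,HDL,2,-0.14,0.06,0.018
rs17482753,LDL,2,0.03,0.06,0.662
rs17482753,VLDL,2,0.21,0.06,0.0005
rs1800961,TG,1,-0.05,0.11,0.668
rs1800961,TC,1,-0.23,0.11,0.038
rs1800961,HDL,1,-0.23,0.11,0.040
rs1800961,LDL,1,-0.15,0.11,0.176
rs1800961,VLDL,1,-0.05,0.11,0.668
rs1800961,TG,2,-0.06,0.11,0.585
rs1800961,TC,2,-0.21,0.12,0.066
rs1800961,HDL,2,-0.22,0.11,0.055
rs1800961,LDL,2,-0.13,0.12,0.260
rs1800961,VLDL,2,-0.06,0.11,0.585
rs2293889,TG,1,0.08,0.03,0.023
rs2293889,TC,1,0.08,0.03,0.013
rs2293889,HDL,1,-0.06,0.03,0.094
rs2293889,LDL,1,0.09,0.03,0.005
rs2293889,VLDL,1,0.08,0.03,0.023
rs2293889,TG,2,0.08,0.03,0.015
rs2293889,TC,2,0.10,0.03,0.004
rs2293889,HDL,2,-0.06,0.03,0.062
rs2293889,LDL,2,0.11,0.03,0.001
rs2293889,VLDL,2,0.08,0.03,0.015
rs2814944,TG,1,0.05,0.05,0.370
rs2814944,TC,1,-0.03,0.05,0.583
rs2814944,HDL,1,0.07,0.05,0.152
rs2814944,LDL,1,-0.02,0.05,0.633
rs2814944,VLDL,1,0.05,0.05,0.370
rs2814944,TG,2,0.06,0.05,0.233
rs2814944,TC,2,0.00,0.05,0.937
rs2814944,HDL,2,0.04,0.05,0.440
rs2814944,LDL,2,-0.06,0.05,0.235
rs2814944,VLDL,2,0.06,0.05,0.233
rs4147536,TG,1,0.04,0.04,0.259
rs4147536,TC,1,0.10,0.04,0.004
rs4147536,HDL,1,0.06,0.04,0.092
rs4147536,LDL,1,0.10,0.04,0.007
rs4147536,VLDL,1,0.04,0.04,0.259
rs4147536,TG,2,0.05,0.04,0.187
rs4147536,TC,2,0.12,0.04,0.001
rs4147536,HDL,2,0.09,0.04,0.014
rs4147536,LDL,2,0.10,0.04,0.006
rs4147536,VLDL,2,0.05,0.04,0.187
rs4148005,TG,1,0.09,0.03,0.010
rs4148005,TC,1,-0.04,0.03,0.299
rs4148005,HDL,1,-0.13,0.03,0.0005
rs4148005,LDL,1,-0.05,0.03,0.187
rs4148005,VLDL,1,0.09,0.03,0.010
rs4148005,TG,2,0.11,0.04,0.001
rs4148005,TC,2,-0.01,0.04,0.814
rs4148005,HDL,2,-0.13,0.03,0.0005
rs4148005,LDL,2,-0.02,0.04,0.482
rs4148005,VLDL,2,0.11,0.04,0.001
rs4420638,TG,1,0.11,0.05,0.027
rs4420638,TC,1,0.08,0.05,0.123
rs4420638,HDL,1,-0.17,0.05,0.0005
rs4420638,LDL,1,0.13,0.05,0.009
rs4420638,VLDL,1,0.11,0.05,0.027
rs4420638,TG,2,0.10,0.05,0.044
rs4420638,TC,2,0.07,0.05,0.191
rs4420638,HDL,2,-0.15,0.05,0.003
rs4420638,LDL,2,0.11,0.05,0.028
rs4420638,VLDL,2,0.10,0.05,0.044
rs660240,TG,1,-0.01,0.04,0.734
rs660240,TC,1,0.09,0.04,0.013
rs660240,HDL,1,-0.01,0.04,0.734
rs660240,LDL,1,0.12,0.04,0.001
rs660240,VLDL,1,-0.01,0.04,0.734
rs660240,TG,2,0.00,0.04,0.933
rs660240,TC,2,0.07,0.04,0.059
rs660240,HDL,2,-0.01,0.04,0.830
rs660240,LDL,2,0.08,0.04,0.020
rs660240,VLDL,2,0.00,0.04,0.933
rs737337,TG,1,0.05,0.04,0.300
rs737337,TC,1,-0.04,0.04,0.417
rs737337,HDL,1,-0.08,0.04,0.068
rs737337,LDL,1,-0.04,0.04,0.410
rs737337,VLDL,1,0.05,0.04,0.300
rs737337,TG,2,0.01,0.05,0.767
rs737337,TC,2,-0.03,0.05,0.533
rs737337,HDL,2,-0.06,0.05,0.188
rs737337,LDL,2,-0.02,0.05,0.716
rs737337,VLDL,2,0.01,0.05,0.767
rs7832643,TG,1,-0.02,0.03,0.600
rs7832643,TC,1,-0.04,0.03,0.174
rs7832643,HDL,1,-0.11,0.03,0.001
rs7832643,LDL,1,-0.01,0.03,0.761
rs7832643,VLDL,1,-0.02,0.03,0.600
rs7832643,TG,2,-0.02,0.03,0.507
rs7832643,TC,2,-0.04,0.03,0.279
rs7832643,HDL,2,-0.09,0.03,0.004
rs7832643,LDL,2,-0.01,0.03,0.879
rs7832643,VLDL,2,-0.02,0.03,0.507
GRS,TG,1,0.10,0.02,0.0005
GRS,TC,1,0.09,0.02,0.0005
GRS,HDL,1,-0.11,0.01,0.0005
GRS,LDL,1,0.11,0.02,0.0005
GRS,VLDL,1,0.10,0.02,0.0005
wGRS,TG,1,0.95,0.16,0.0005
wGRS,TC,1,1.01,0.23,0.0005
wGRS,HDL,1,-0.87,0.14,0.0005
wGRS,LDL,1,1.03,0.19,0.0005
wGRS,VLDL,1,0.95,0.16,0.0005
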