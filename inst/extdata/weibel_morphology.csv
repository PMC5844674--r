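gn,radius_m,length_m,t_epi_m,t_conn_m,t_asm_m
0,0.0090,0.1200,4.50e-04,9.00e-04,1.350e-03
1,0.0061,0.0476,3.05e-04,6.10e-04,9.150e-04
2,0.00415,0.0190,2.075e-04,4.15e-04,6.225e-04
3,0.0028,0.0076,1.40e-04,2.80e-04,4.20e-04
4,0.00225,0.0127,1.125e-04,2.25e-04,3.375e-04
5,0.00175,0.0107,8.75e-05,1.75e-04,2.625e-04
6,0.0014,0.0090,7.00e-05,1.40e-04,2.10e-04
7,0.00115,0.0076,5.75e-05,1.15e-04,1.725e-04
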