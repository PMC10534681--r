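version,d_in,d_out,d_out_d_in,H_in,H_out,H_in_H_out,theta,D_t,D_b,H_b,H
1,2.05,3.61,1.76,7.44,8.70,0.85,90,12.18,,,43.96
2,2.61,5.34,2.04,4.30,3.00,1.43,<90,14.27,,,30.17
3,1.29,2.9,2.24,13.0,13.0,1.00,<90,14.37,20,9.30,28.08
4,1.26,2.95,2.34,10.8,11.5,0.93,90,14.37,20,7.15,20.14
5,2.43,5.00,2.05,10.1,5.60,1.80,<90,13.38,20,12.72,18.63
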