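station,date,vlp_foam,vlp_sml,vlp_ssw,vlp_prc,prok_foam,prok_sml,prok_ssw,prok_prc,euk_foam,euk_sml,euk_ssw,printed_ef_vlp,printed_ef_prok,printed_ef_euk,printed_ratio_foam,printed_ratio_sml,printed_ratio_ssw,printed_ratio_prc
1,2020-02-03,n.d.,1.8E+07,1.9E+07,n.d.,n.d.,7.9E+05,8.0E+05,n.d.,n.d.,3.3E+03,3.4E+03,0.9,1.0,1.0,n.d.,22.4,23.5,n.d.
2,2020-02-04,n.d.,1.7E+07,1.7E+07,n.d.,n.d.,8.5E+05,8.4E+05,n.d.,n.d.,4.5E+03,4.3E+03,1.0,1.0,1.0,n.d.,19.4,20.0,n.d.
3,2020-02-06,n.d.,1.7E+07,1.6E+07,n.d.,n.d.,7.9E+05,7.9E+05,n.d.,n.d.,2.1E+03,2.1E+03,1.0,1.0,1.0,n.d.,21.2,20.4,n.d.
4,2020-02-07,1.8E+08,2.6E+07,1.4E+07,n.d.,3.8E+06,8.0E+05,7.5E+05,n.d.,1.8E+04,3.4E+03,3.4E+03,1.8,1.1,1.0,48.4,32.5,19.3,n.d.
12/R,2020-02-10,n.d.,n.d.,n.d.,6.5E+04,n.d.,n.d.,n.d.,9.1E+03,n.d.,n.d.,n.d.,n.d.,n.d.,n.d.,n.d.,n.d.,n.d.,7.1
5,2020-02-11,n.d.,1.3E+07,1.9E+07,n.d.,n.d.,8.5E+05,8.7E+05,n.d.,n.d.,3.2E+03,5.0E+03,0.7,1.0,0.6,n.d.,15.5,21.7,n.d.
6,2020-02-13,5.0E+07,1.6E+07,1.9E+07,n.d.,1.3E+06,8.0E+05,7.8E+05,n.d.,3.4E+03,3.5E+03,3.0E+03,0.9,1.0,1.2,39.4,20.2,24.4,n.d.
7,2020-02-14,n.d.,1.9E+07,2.0E+07,n.d.,n.d.,7.0E+05,7.5E+05,n.d.,n.d.,1.8E+03,3.4E+03,0.9,0.9,0.5,n.d.,26.8,26.7,n.d.
8,2020-02-15,7.7E+07,3.4E+07,1.9E+07,n.d.,3.0E+06,9.9E+05,7.6E+05,n.d.,1.8E+04,6.2E+03,4.2E+03,1.8,1.3,1.5,25.3,34.2,24.4,n.d.
12/R,2020-02-16,n.d.,n.d.,n.d.,3.7E+04,n.d.,n.d.,n.d.,3.9E+03,n.d.,n.d.,n.d.,n.d.,n.d.,n.d.,n.d.,n.d.,n.d.,9.5
9,2020-02-19,n.d.,3.1E+07,1.6E+07,n.d.,n.d.,1.1E+06,8.3E+05,n.d.,n.d.,5.6E+03,4.5E+03,1.9,1.3,1.2,n.d.,28.1,19.8,n.d.
12/R,2020-02-21,n.d.,n.d.,n.d.,1.2E+05,n.d.,n.d.,n.d.,7.9E+03,n.d.,n.d.,n.d.,n.d.,n.d.,n.d.,n.d.,n.d.,n.d.,14.9
12/R,2020-02-22,n.d.,n.d.,n.d.,2.7E+05,n.d.,n.d.,n.d.,1.8E+04,n.d.,n.d.,n.d.,n.d.,n.d.,n.d.,n.d.,n.d.,n.d.,14.8
10,2020-02-24,5.5E+07,2.0E+07,1.9E+07,n.d.,1.5E+06,9.2E+05,8.5E+05,n.d.,6.1E+03,3.9E+03,3.9E+03,1.1,1.1,1.0,36.2,21.9,22.1,n.d.
11,2020-02-26,n.d.,n.d.,1.5E+07,n.d.,n.d.,n.d.,7.0E+05,n.d.,n.d.,n.d.,2.1E+03,n.d.,n.d.,n.d.,n.d.,n.d.,21.6,n.d.
12/R,2020-02-26,n.d.,n.d.,n.d.,3.4E+05,n.d.,n.d.,n.d.,2.7E+03,n.d.,n.d.,n.d.,n.d.,n.d.,n.d.,n.d.,n.d.,n.d.,127.8
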