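# units: M
# mode: host_titration
host_total_M,indicator_total_M,competitor_total_M,signal
0,1.16e-06,0,2.46939654777249
6e-06,1.16e-06,0,8.65604010540612
1.2e-05,1.16e-06,0,9.91744620926055
1.8e-05,1.16e-06,0,10.4074743247551
2.4e-05,1.16e-06,0,10.6283486973043
3e-05,1.16e-06,0,10.7245045166787
3.6e-05,1.16e-06,0,11.0016842235417
4.2e-05,1.16e-06,0,10.9012180759565
4.8e-05,1.16e-06,0,11.1886298490817
5.4e-05,1.16e-06,0,11.0039634397725
6e-05,1.16e-06,0,11.190056148296
6.6e-05,1.16e-06,0,11.3279508593744
7.2e-05,1.16e-06,0,10.94463265764
7.8e-05,1.16e-06,0,11.088198901987
8.4e-05,1.16e-06,0,11.1218911578235
9e-05,1.16e-06,0,11.2228909346165
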