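subject,condition,vlf_pct,lf_pct,hf_pct,lf_hf_ratio
1,baseline,30.3,15.2,46.2,0.354
1,AD,36.8,15.8,38.5,0.443
2,baseline,56.3,4.1,34.3,0.186
2,AD,39.1,10.8,32.9,0.355
3,baseline,45.1,11.0,32.6,0.345
3,AD,47.1,12.6,28.3,0.564
4,baseline,49.8,9.9,28.9,0.492
4,AD,48.7,8.7,31.9,0.309
5,baseline,31.7,8.7,25.4,0.432
5,AD,62.5,10.6,25.3,0.395
6,baseline,46.4,19.2,30.9,0.656
6,AD,78.4,6.6,13.5,0.498
7,baseline,12.9,13.2,58.7,0.225
7,AD,16.1,14.8,54.6,0.270
8,baseline,27.9,16.3,47.0,0.368
8,AD,34.7,17.5,40.2,0.499
9,baseline,39.6,7.3,47.1,0.196
9,AD,34.4,10.9,43.3,0.316
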