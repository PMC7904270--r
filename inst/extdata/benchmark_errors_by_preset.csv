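preset,delta,H,V,C
1,1,6.4,4.0,7.5
2,1,6.4,3.9,7.5
3,1,6.0,4.1,7.3
4,1,5.8,4.0,7.0
5,1,6.2,4.6,7.7
6,1,6.1,4.5,7.6
1,2,6.3,3.9,7.4
2,2,6.2,3.8,7.3
3,2,5.8,4.1,7.1
4,2,5.7,4.0,7.0
5,2,6.1,4.6,7.6
6,2,5.9,4.4,7.4
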