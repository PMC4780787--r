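((((a:0.5)#H1:0.3::0.7,(b:1,c:1):0.6):0.5,(#H1:0.4::0.3,d:1):0.7):0.4,(e:1,f:1):0.3);
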