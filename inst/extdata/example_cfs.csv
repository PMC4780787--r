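taxon1,taxon2,taxon3,taxon4,CF12_34,CF13_24,CF14_23,ngenes
a,b,c,d,0.133,0.145,0.722,3000
a,b,c,e,0.153333333333333,0.159666666666667,0.687,3000
a,b,c,f,0.152,0.163666666666667,0.684333333333333,3000
a,b,d,e,0.457333333333333,0.339333333333333,0.203333333333333,3000
a,b,d,f,0.454666666666667,0.342666666666667,0.202666666666667,3000
a,b,e,f,0.76,0.122333333333333,0.117666666666667,3000
a,c,d,e,0.461333333333333,0.338,0.200666666666667,3000
a,c,d,f,0.461666666666667,0.338,0.200333333333333,3000
a,c,e,f,0.767,0.116666666666667,0.116333333333333,3000
a,d,e,f,0.721666666666667,0.134333333333333,0.144,3000
b,c,d,e,0.785333333333333,0.110333333333333,0.104333333333333,3000
b,c,d,f,0.782,0.108,0.11,3000
b,c,e,f,0.893,0.0516666666666667,0.0553333333333333,3000
b,d,e,f,0.677333333333333,0.154666666666667,0.168,3000
c,d,e,f,0.68,0.157666666666667,0.162333333333333,3000
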