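channel,fasting_variance,glucose_variance,t,p
1,0.208,0.203,-1.01,0.156
2,0.154,0.160,-0.92,0.18
3,0.221,0.231,-0.406,0.343
4,0.176,0.184,0.0837,0.467
5,0.170,0.177,0.899,0.184
6,0.190,0.186,0.666,0.253
7,0.138,0.141,-1.91,0.0278
8,0.217,0.195,0.258,0.395
9,0.195,0.186,-0.179,0.429
10,0.204,0.173,-0.0500,0.480
11,0.170,0.171,-0.73,0.233
12,0.151,0.148,-2.45,0.00713
13,0.156,0.148,0.973,0.165
14,0.170,0.152,-1.28,0.0997
15,0.224,0.227,-2.3,0.0107
16,0.168,0.147,-1.13,0.127
17,0.181,0.165,-1.28,0.101
18,0.179,0.170,1.66,0.0483
19,0.196,0.195,-1.77,0.0382
20,0.247,0.220,1.03,0.151
21,0.213,0.233,0.179,0.429
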