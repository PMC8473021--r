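variable,quotient,rank
X04,1.0126,1
X02,1.0125,2
X15,1.0122,3
X18,1.0057,4
X11,1.0051,5
X12,1.0051,6
X20,1.0024,7
X14,1.0010,8
X03,1.0010,9
X16,1.0010,10
X08,1.0009,11
X19,1.0008,12
X17,1.0004,13
X10,1.0004,14
SEX,1.0003,15
X06,1.0002,16
X01,1.0002,17
X07,1.0001,18
X09,1.0001,19
X21,1.0001,20
X05,1.0000,21
X13,0.9999,22
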